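# JSON (de)serialization of fitted models. Doubles are written with 17
# significant digits so thresholds, eigenfunctions and scores round-trip
# exactly and a reloaded model predicts identically.

json_write <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null")
  invisible(path)
}

fpca_to_list <- function(model) {
  list(type = "fpca", grid = model$grid, mean = model$mean,
       efuns = model$efuns, values = model$values,
       total_variance = model$total_variance, K = model$K,
       scores = model$scores, labels = model$labels)
}

fpca_from_list <- function(x) {
  structure(list(grid = as.numeric(x$grid), mean = as.numeric(x$mean),
                 efuns = as.matrix(x$efuns), values = as.numeric(x$values),
                 total_variance = as.numeric(x$total_variance),
                 weights = trapezoid_weights(as.numeric(x$grid)),
                 K = as.integer(x$K),
                 scores = if (is.null(x$scores)) NULL else as.matrix(x$scores),
                 labels = if (is.null(x$labels)) NULL else as.character(x$labels)),
            class = "fpca")
}

basis_to_list <- function(basis) {
  list(type = "bspline_basis", grid = basis$grid, order = basis$order,
       nbasis = basis$nbasis)
}

basis_from_list <- function(x) {
  bspline_basis(as.numeric(x$grid), nbasis = as.integer(x$nbasis),
                order = as.integer(x$order))
}

node_to_list <- function(nd) {
  list(id = nd$id, parent = nd$parent, depth = nd$depth, is_leaf = nd$is_leaf,
       n = nd$n, counts = as.integer(nd$counts), pred = nd$pred,
       members = as.integer(nd$members), feature = nd$feature,
       threshold = nd$threshold, gain = nd$gain, left = nd$left,
       right = nd$right, leaf = nd$leaf)
}

node_from_list <- function(x) {
  as_int_na <- function(v) if (is.null(v)) NA_integer_ else as.integer(v)
  as_num_na <- function(v) if (is.null(v)) NA_real_ else as.numeric(v)
  list(id = as.integer(x$id), parent = as_int_na(x$parent),
       depth = as.integer(x$depth), is_leaf = isTRUE(x$is_leaf),
       n = as.integer(x$n), counts = as.integer(unlist(x$counts)),
       pred = as.integer(x$pred), members = as.integer(unlist(x$members)),
       feature = as_int_na(x$feature), threshold = as_num_na(x$threshold),
       gain = as_num_na(x$gain), left = as_int_na(x$left),
       right = as_int_na(x$right), leaf = as_int_na(x$leaf))
}

fct_to_list <- function(tree) {
  list(type = "fct", labels = tree$labels, feature_kind = tree$feature_kind,
       p = tree$p, control = unclass(tree$control),
       nodes = lapply(tree$nodes, node_to_list))
}

fct_from_list <- function(x) {
  ctl <- x$control
  control <- fct_control(criterion = ctl$criterion, minsplit = ctl$minsplit,
                         minbucket = ctl$minbucket, cp = ctl$cp,
                         maxdepth = ctl$maxdepth, nfolds = ctl$nfolds)
  structure(list(nodes = lapply(x$nodes, node_from_list),
                 labels = as.character(x$labels), control = control,
                 feature_kind = x$feature_kind, p = as.integer(x$p)),
            class = "fct")
}

frf_to_list <- function(model) {
  list(type = "frf", labels = model$labels, mtry = model$mtry,
       ntree = model$ntree, seed = model$seed, p = model$p,
       feature_kind = model$feature_kind, control = unclass(model$control),
       inbag = model$inbag,
       trees = lapply(model$trees, fct_to_list))
}

frf_from_list <- function(x) {
  # json simplification may turn the equal-length bootstrap vectors into a matrix
  inbag <- if (is.matrix(x$inbag))
    lapply(seq_len(nrow(x$inbag)), function(i) as.integer(x$inbag[i, ]))
  else lapply(x$inbag, function(v) as.integer(unlist(v)))
  trees <- lapply(x$trees, fct_from_list)
  n <- trees[[1]]$nodes[[1]]$n          # bootstrap size = N
  ctl <- x$control
  structure(list(trees = trees, inbag = inbag,
                 oob = lapply(inbag, function(idx) setdiff(seq_len(n), idx)),
                 labels = as.character(x$labels), mtry = as.integer(x$mtry),
                 ntree = as.integer(x$ntree),
                 seed = if (is.null(x$seed)) NULL else as.integer(x$seed),
                 p = as.integer(x$p),
                 control = fct_control(criterion = ctl$criterion,
                                       minsplit = ctl$minsplit,
                                       minbucket = ctl$minbucket, cp = ctl$cp,
                                       maxdepth = ctl$maxdepth,
                                       nfolds = ctl$nfolds),
                 feature_kind = x$feature_kind),
            class = "frf")
}

#' Save a fitted model to JSON
#'
#' Writes an [fpca], [bspline_basis], [fct] or [frf] object (or a bundle: a
#' plain list of such objects plus scalar metadata) to a documented JSON
#' layout with full double precision, so that fitting and prediction can run
#' in separate sessions.
#'
#' @param object the model to save.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(object, path) {
  json_write(model_to_list(object), path)
}

model_to_list <- function(object) {
  if (inherits(object, "fpca")) fpca_to_list(object)
  else if (inherits(object, "bspline_basis")) basis_to_list(object)
  else if (inherits(object, "fct")) fct_to_list(object)
  else if (inherits(object, "frf")) frf_to_list(object)
  else if (is.list(object) && !is.null(object$type) &&
           object$type == "bundle") {
    object$parts <- lapply(object$parts, model_to_list)
    object
  }
  else stop("unsupported object of class ", paste(class(object), collapse = "/"))
}

#' Load a model saved by [write_model()]
#'
#' @param path JSON file path.
#' @return the reconstructed model object (dispatch on the stored `type`).
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                           simplifyMatrix = TRUE)
  model_from_list(x)
}

model_from_list <- function(x) {
  switch(as.character(x$type),
         fpca = fpca_from_list(x),
         bspline_basis = basis_from_list(x),
         fct = fct_from_list(x),
         frf = frf_from_list(x),
         bundle = { x$parts <- lapply(x$parts, model_from_list); x },
         stop("unknown model type: ", x$type))
}
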