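#!/usr/bin/env Rscript
# Optional benchmark on user-supplied ECG data (e.g. the public ECG200 /
# ECG5000 archives in .ts or label-first delimited layout). Not part of the
# acceptance run; requires files the repository does not ship.
#
#   Rscript scripts/ecg_benchmark.R <train-file> <test-file> [K] [max-trees]
#
# Fits FPCA on the training curves, projects the test curves onto the
# training eigenbasis, and prints a grid of functional-random-forest test
# accuracies over forest sizes and numbers of components.

suppressPackageStartupMessages(library(fctree))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 2)
  stop("usage: Rscript scripts/ecg_benchmark.R <train> <test> [K] [max-trees]")
train <- read_curves(args[1])
test <- read_curves(args[2])
K_max <- if (length(args) >= 3) as.integer(args[3]) else 15L
H_grid <- seq(2L, if (length(args) >= 4) as.integer(args[4]) else 50L)

model <- fpca(train, K = K_max)
test_scores_all <- project(model, test)

cat(sprintf("%8s", "trees"),
    sprintf("K=%-5d", 2:K_max), "\n")
for (H in H_grid) {
  acc <- vapply(2:K_max, function(K) {
    f <- frf(model$scores[, 1:K, drop = FALSE], train$labels,
             ntree = H, seed = 1)
    mean(as.character(predict(f, test_scores_all[, 1:K, drop = FALSE])) ==
           test$labels)
  }, numeric(1))
  cat(sprintf("%8d", H), sprintf("%-7.2f", 100 * acc), "\n")
}
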