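## End-to-end orchestration and evaluation: simulate -> extract -> train ->
## genotype, the copy-number x coverage accuracy grid, and the
## equal-probability invalid-sample accounting.

#' Evaluate genotype calls against truth labels
#'
#' Overall accuracy counts equal-probability ties as errors; ties are the
#' *invalid samples*, and the valid-sample accuracy is recomputed over the
#' remainder: `valid = correct / (n - n_invalid)`.
#'
#' @param calls a [genotype_calls()] frame.
#' @param truth character vector of true classes, or an [sv_calls()] frame
#'   with a `gtclass` column; aligned to `calls` by `call_id` when ids are
#'   available.
#' @return List of class `sv_evaluation`: `n_samples`, `n_invalid`,
#'   `overall_accuracy`, `valid_accuracy`, and the 5x5 `confusion` matrix
#'   (rows = truth).
#' @export
evaluate_genotypes <- function(calls, truth) {
  if (is.data.frame(truth)) {
    if (is.null(truth$gtclass)) stop("evaluate_genotypes: truth has no gtclass")
    m <- match(calls$call_id, truth$id)
    if (any(is.na(m))) stop("evaluate_genotypes: call ids not found in truth")
    truth <- truth$gtclass[m]
  }
  if (length(truth) != nrow(calls))
    stop("evaluate_genotypes: calls/truth length mismatch")
  n <- nrow(calls)
  correct <- calls$label == truth & !calls$is_tie
  n_invalid <- sum(calls$is_tie)
  lev <- GENOTYPE_CLASSES
  confusion <- table(factor(truth, lev), factor(calls$label, lev))
  out <- list(n_samples = n, n_invalid = n_invalid,
              overall_accuracy = sum(correct) / n,
              valid_accuracy = if (n > n_invalid)
                sum(correct) / (n - n_invalid) else NA_real_,
              confusion = confusion)
  class(out) <- "sv_evaluation"
  out
}

#' @export
print.sv_evaluation <- function(x, ...) {
  cat(sprintf("samples: %d  invalid (tie): %d\n", x$n_samples, x$n_invalid))
  cat(sprintf("overall accuracy: %.4f  valid-sample accuracy: %.4f\n",
              x$overall_accuracy, x$valid_accuracy))
  print(x$confusion)
  invisible(x)
}

#' Valid-sample accuracy from summary figures
#'
#' Recovers the correct-call count from a printed overall accuracy by
#' nearest-integer rounding and rescales over the valid (non-tie) samples:
#' `round(overall * n) / (n - n_invalid)`.
#'
#' @param overall_accuracy overall accuracy (ties counted as errors).
#' @param n_samples total sample count.
#' @param n_invalid number of equal-probability (tie) samples.
#' @return Valid-sample accuracy.
#' @export
valid_sample_accuracy <- function(overall_accuracy, n_samples, n_invalid) {
  round(overall_accuracy * n_samples) / (n_samples - n_invalid)
}

#' Simulate, extract features and label one dataset
#'
#' Convenience wrapper: runs the simulator and returns the feature matrix
#' and the truth labels, ready for [mrvm()].
#'
#' @param cfg a [sim_config()].
#' @return list with `features` (`sv_features`), `labels` (character),
#'   `truth`, `alignments`.
#' @export
simulate_training_set <- function(cfg) {
  sim <- simulate_sv_data(cfg, write_fastq = FALSE)
  stats <- insert_stats(cfg$insert_mu, cfg$insert_sigma)
  feat <- extract_features(sim$truth, sim$alignments, stats = stats,
                           read_length = cfg$read_length,
                           reference_length = cfg$region_length)
  list(features = feat, labels = sim$truth$gtclass, truth = sim$truth,
       alignments = sim$alignments)
}

#' Copy-number by coverage accuracy grid
#'
#' For every (copy number, coverage) cell, simulates `repeats` independent
#' train/test dataset pairs under identical configuration but distinct
#' derived seeds, trains an mRVM on the training set and measures five-class
#' accuracy on the test set; reports per-cell means over repeats.
#'
#' @param copy_numbers,coverages grid axes.
#' @param repeats independent repeats per cell.
#' @param base_config a [sim_config()] providing all other parameters.
#' @param seed base seed; each (cell, repeat, role) seed is derived from it.
#' @param kernel_param,max_iter passed to [mrvm()].
#' @param verbose print per-cell progress.
#' @return Data frame of class `sv_grid`: `copy_number`, `coverage`,
#'   `accuracy` (mean), `sd`, `mean_rv` (final relevance vectors),
#'   `valid_accuracy`, plus a `repeats` attribute with the per-repeat log.
#' @export
run_grid_experiment <- function(copy_numbers = 2:5,
                                coverages = c(5, 10, 15, 20),
                                repeats = 5,
                                base_config = sim_config(),
                                seed = 1,
                                kernel_param = 5,
                                max_iter = 500,
                                verbose = FALSE) {
  stopifnot(repeats >= 1)
  cells <- expand.grid(copy_number = copy_numbers, coverage = coverages)
  log <- vector("list", 0)
  res <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    cn <- cells$copy_number[ci]; cov <- cells$coverage[ci]
    acc <- numeric(repeats); vacc <- numeric(repeats); nrv <- numeric(repeats)
    for (r in seq_len(repeats)) {
      cfg <- base_config
      cfg$copy_number <- as.integer(cn); cfg$coverage <- cov
      cfg_train <- cfg; cfg_train$seed <- derive_seed(seed, cn, cov, r, 1)
      cfg_test <- cfg;  cfg_test$seed <- derive_seed(seed, cn, cov, r, 2)
      tr <- simulate_training_set(cfg_train)
      te <- simulate_training_set(cfg_test)
      fit <- mrvm(tr$features, tr$labels, kernel_param = kernel_param,
                  max_iter = max_iter)
      calls <- predict(fit, te$features, type = "call")
      ev <- evaluate_genotypes(calls, te$truth)
      acc[r] <- ev$overall_accuracy
      vacc[r] <- ev$valid_accuracy
      nrv[r] <- nrow(fit$weights)
      log[[length(log) + 1]] <- data.frame(
        copy_number = cn, coverage = cov, repeat_ = r,
        seed_train = cfg_train$seed, seed_test = cfg_test$seed,
        accuracy = acc[r], valid_accuracy = vacc[r], n_rv = nrv[r])
    }
    res[[ci]] <- data.frame(copy_number = cn, coverage = cov,
                            accuracy = mean(acc), sd = stats::sd(acc),
                            valid_accuracy = mean(vacc), mean_rv = mean(nrv))
    if (verbose)
      message(sprintf("cn=%d cov=%gx: accuracy %.4f", cn, cov, mean(acc)))
  }
  out <- do.call(rbind, res)
  attr(out, "repeats") <- do.call(rbind, log)
  class(out) <- c("sv_grid", "data.frame")
  out
}

#' Genotype candidate calls from alignments with a fitted model
#'
#' Extracts features for the candidate calls and predicts the five-class
#' genotype. Optionally writes an annotated VCF (INFO `GTCLASS` plus the
#' five probabilities) and a TSV of the probability table.
#'
#' @param calls an [sv_calls()] frame or VCF path.
#' @param alignments alignment frame or SAM/BAM path.
#' @param model a fitted [mrvm()].
#' @param stats optional [insert_stats()]; estimated from the file if absent.
#' @param read_length read length in bp.
#' @param vcf_out,tsv_out optional output paths.
#' @return A [genotype_calls()] frame.
#' @export
genotype_sv <- function(calls, alignments, model, stats = NULL,
                        read_length = 100, vcf_out = NULL, tsv_out = NULL) {
  if (is.character(calls)) calls <- read_sv_vcf(calls)
  if (nrow(calls) == 0) {
    empty <- genotype_calls(matrix(numeric(0), 0, 5,
                                   dimnames = list(NULL, GENOTYPE_CLASSES)),
                            ids = character(0))
    if (!is.null(tsv_out)) utils::write.table(empty, tsv_out, sep = "\t",
                                              quote = FALSE, row.names = FALSE)
    return(empty)
  }
  feat <- extract_features(calls, alignments, stats = stats,
                           read_length = read_length)
  probs <- predict(model, feat, type = "prob")
  out <- genotype_calls(probs, ids = calls$id)
  if (!is.null(vcf_out)) {
    ann <- calls
    ann$gtclass <- out$label
    write_sv_vcf(ann, vcf_out,
                 info_extra = stats::setNames(
                   lapply(model$levels, function(l) round(out[[paste0("p_", l)]], 6)),
                   paste0("P", model$levels)))
  }
  if (!is.null(tsv_out))
    utils::write.table(out, tsv_out, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

#' Relevance-vector trace report
#'
#' @param model a fitted [mrvm()].
#' @param csv_out optional CSV path for the machine-readable trace.
#' @param plot draw the trace.
#' @return The trace data frame (`iteration`, `n_rv`, `delta`), invisibly
#'   when plotting.
#' @export
trace_report <- function(model, csv_out = NULL, plot = FALSE) {
  tr <- model$trace
  if (is.null(tr) || nrow(tr) == 0) stop("trace_report: empty training trace")
  if (!is.null(csv_out)) utils::write.csv(tr, csv_out, row.names = FALSE)
  if (plot) plot(model)
  tr
}
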