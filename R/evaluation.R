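#' Randomly split patients into partitions with exact apportioned sizes
#'
#' Partition sizes follow largest-remainder apportionment: each partition
#' gets `floor(n * ratio)` patients and the remainder goes one by one to the
#' partitions with the largest fractional parts (ties to the earlier
#' partition). This convention reproduces, e.g., 659 patients at
#' 70/15/15 -> 461/99/99 and 316 at 20/80 -> 63/253. Membership is
#' randomised by the seed.
#'
#' @param patients number of patients or character vector of patient ids.
#' @param ratios positive ratios summing to 1.
#' @param seed integer seed.
#' @param names optional partition names (default "part1", ... or
#'   train/val/test style names supplied by the caller).
#' @return Object of class `patient_split`: `sizes`, `assignment`
#'   (data.frame patient_id / partition), `ratios`, `seed`.
#' @examples
#' split_patients(659, c(0.70, 0.15, 0.15), seed = 1)$sizes
#' @export
split_patients <- function(patients, ratios, seed = 1L, names = NULL) {
  if (length(patients) == 1L && is.numeric(patients))
    patients <- sprintf("S%04d", seq_len(patients))
  n <- length(patients)
  if (any(ratios <= 0) || abs(sum(ratios) - 1) > 1e-9)
    stop_arg("ratios must be positive and sum to 1")
  k <- length(ratios)
  if (n < k) stop_arg("fewer patients than partitions")
  base <- floor(n * ratios)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * ratios - base
    # largest fractional parts first, ties to earlier partitions
    extra <- order(-frac, seq_len(k))[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  sizes <- as.integer(base)
  if (is.null(names)) names <- paste0("part", seq_len(k))
  names(sizes) <- names
  assignment <- withr::with_seed(seed, {
    perm <- sample(patients)
    data.frame(patient_id = perm,
               partition = rep(names, sizes), stringsAsFactors = FALSE)
  })
  structure(list(sizes = sizes, assignment = assignment, ratios = ratios,
                 seed = seed),
            class = "patient_split")
}

#' @export
print.patient_split <- function(x, ...) {
  cat("patient split:", paste(sprintf("%s=%d", names(x$sizes), x$sizes),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Write a patient split to TSV
#' @param split a `patient_split`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_split_tsv <- function(split, path) {
  utils::write.table(split$assignment, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Area under the ROC curve
#'
#' Computed by the rank (Mann–Whitney) formula with midrank tie handling, so
#' the value equals the probability that a positive patient outscores a
#' negative one plus half the probability of a tie.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @examples
#' auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop_arg("AUC undefined: only one class present")
  r <- rank(scores)   # midranks for ties
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Bootstrap percentile confidence interval for the AUC
#'
#' Patients are resampled with replacement `n_boot` times (default 1000);
#' replicates that draw a single class are redrawn so exactly `n_boot`
#' replicate AUCs enter the interval. The 95% interval is the 2.5th and
#' 97.5th percentile of the replicates.
#'
#' @param scores,labels as in [auc()].
#' @param n_boot number of bootstrap replicates.
#' @param seed integer seed; intervals are seed-reproducible.
#' @param conf confidence level.
#' @return Named vector `c(low, high)`.
#' @export
bootstrap_ci <- function(scores, labels, n_boot = 1000L, seed = 1L,
                         conf = 0.95) {
  labels <- as.integer(labels)
  n <- length(scores)
  stopifnot(n == length(labels))
  auc(scores, labels)  # validates both classes present
  reps <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2L)
          return(auc(scores[idx], labels[idx]))
      }
    }, 0)
  })
  q <- stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                       names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}

#' Evaluate per-patient scores: AUC with bootstrap confidence interval
#'
#' @param scores,labels as in [auc()].
#' @param n_boot bootstrap replicates for the interval.
#' @param seed seed for the bootstrap.
#' @return Object of class `eval_result`: `auc`, `ci_low`, `ci_high`,
#'   `n_boot`, `scores`, `labels`.
#' @export
evaluate_scores <- function(scores, labels, n_boot = 1000L, seed = 1L) {
  a <- auc(scores, labels)
  ci <- bootstrap_ci(scores, labels, n_boot = n_boot, seed = seed)
  structure(list(auc = a, ci_low = ci[["low"]], ci_high = ci[["high"]],
                 n_boot = as.integer(n_boot), scores = scores,
                 labels = as.integer(labels)),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f, %d bootstrap replicates, n = %d)\n",
              x$auc, x$ci_low, x$ci_high, x$n_boot, length(x$labels)))
  invisible(x)
}

#' Write an evaluation result to JSON
#' @param result an `eval_result`.
#' @param path output path.
#' @param task optional task name recorded in the file.
#' @return Invisibly, `path`.
#' @export
write_eval_json <- function(result, path, task = NA_character_) {
  jsonlite::write_json(
    list(task = task, auc = result$auc, ci_low = result$ci_low,
         ci_high = result$ci_high, n_boot = result$n_boot,
         n_test = length(result$labels)),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
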