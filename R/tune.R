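# The tuning workflow: predict the AUC of each candidate weight set from
# the training summary statistics and select the hyperparameter with the
# best predicted AUC. The command-line wrapper in inst/cli/prsauc calls
# these functions.

#' Tune PRS hyperparameters from training summary statistics
#'
#' Harmonizes each candidate weight set with the summary statistics,
#' predicts its out-of-sample AUC (EM path for independent pre-selected
#' SNPs, SAME path under LD) and returns the per-hyperparameter
#' predictions with the argmax selection. All candidate weight sets must
#' come from the same PRS method family, i.e. share the mode.
#'
#' When the summary statistics originate from a meta-analysis, reported
#' study-wide sample sizes can overstate the per-SNP sample sizes, which
#' biases the predicted AUC downward; the AUC ranking across
#' hyperparameters is much less affected. A note to this effect is
#' emitted whenever per-SNP sample sizes are constant.
#'
#' @param ss a [sumstats] object over the pre-selected SNPs.
#' @param weights list of [weightset] objects (one per hyperparameter
#'   value), or a single weight set.
#' @param mode `"independent"` (EM + closed-form posterior) or `"ld"`
#'   (SAME Gibbs sampler; requires `ld`).
#' @param ld an [ld_structure] aligned to `ss` (mode `"ld"`).
#' @param n_draws Monte-Carlo draws for the independent path.
#' @param schedule [same_schedule()] for the LD path.
#' @param seed optional integer seed.
#' @return list of class `"prs_tuning"`: `table` (one row per weight
#'   set: method, hyperparameter, predicted AUC with 95% interval),
#'   `selected` (row index of the best predicted AUC), `predictions`
#'   (the underlying [auc_prediction] objects).
#' @export
prs_tune <- function(ss, weights, mode = c("independent", "ld"), ld = NULL,
                     n_draws = 1000, schedule = same_schedule(),
                     seed = NULL) {
  mode <- match.arg(mode)
  if (inherits(weights, "weightset")) weights <- list(weights)
  if (!length(weights)) stop("prs_tune: no weight sets supplied", call. = FALSE)
  if (mode == "ld" && is.null(ld))
    stop("prs_tune: mode 'ld' requires an LD structure", call. = FALSE)

  harm <- lapply(weights, function(w) harmonize(ss, w))
  ids <- harm[[1]]$sumstats$snp_id
  same_support <- all(vapply(harm, function(h)
    identical(h$sumstats$snp_id, ids), logical(1)))
  if (!same_support)
    stop("prs_tune: weight sets cover different SNP sets after ",
         "harmonization; tune each family separately", call. = FALSE)
  ss_h <- harm[[1]]$sumstats
  wlist <- lapply(harm, `[[`, "weights")

  if (length(unique(ss_h$n0 + ss_h$n1)) == 1L)
    message("prs_tune: study-wide sample sizes applied to every SNP; if ",
            "these are meta-analysis totals the predicted AUC may be ",
            "underestimated (the ranking across hyperparameters is robust)")

  preds <- if (mode == "independent")
    predict_auc_independent(ss_h, wlist, n_draws = n_draws, seed = seed)
  else predict_auc_ld(ss_h, wlist, ld, schedule = schedule, seed = seed)

  tab <- do.call(rbind, lapply(seq_along(preds), function(k) {
    hyper <- attr(weights[[k]], "hyperparameter")
    data.frame(
      method = attr(weights[[k]], "method_label"),
      hyperparameter = if (length(hyper))
        paste(names(hyper), unlist(hyper), sep = "=", collapse = ",")
        else "",
      auc = preds[[k]]$auc_mean, auc_lo = preds[[k]]$ci[1],
      auc_hi = preds[[k]]$ci[2], stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, selected = which.max(tab$auc),
                 predictions = preds),
            class = "prs_tuning")
}

#' @export
print.prs_tuning <- function(x, ...) {
  tab <- x$table
  tab$auc <- sprintf("%.4f", tab$auc)
  tab$interval <- sprintf("[%.4f, %.4f]", x$table$auc_lo, x$table$auc_hi)
  print(tab[, c("method", "hyperparameter", "auc", "interval")],
        row.names = FALSE)
  cat("selected:", x$table$method[x$selected],
      x$table$hyperparameter[x$selected], "\n")
  invisible(x)
}
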