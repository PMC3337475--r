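# interval utilities (0-based half-open throughout) ---------------------------

# total overlap of interval [s, e) with a set of intervals (matrix cols s, e)
overlap_with_set <- function(s, e, set_s, set_e) {
  if (length(set_s) == 0L) return(0L)
  sum(pmax(0L, pmin(e, set_e) - pmax(s, set_s)))
}

# bp covered by the union of intervals
union_coverage <- function(s, e) {
  if (length(s) == 0L) return(0L)
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  tot <- 0L
  cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] <= cur_e) {
      cur_e <- max(cur_e, e[i])
    } else {
      tot <- tot + (cur_e - cur_s)
      cur_s <- s[i]; cur_e <- e[i]
    }
  }
  tot + (cur_e - cur_s)
}

#' Fraction of a region covered by intervals
#'
#' Union coverage of a set of intervals divided by a total length, on the
#' percent scale with half-up rounding — the convention used for summary
#' statements such as "the experimental modules cover 32.4% of the
#' sequence".
#'
#' @param intervals Data frame with `start`, `end` (0-based half-open).
#' @param total_len Total sequence length in bp.
#' @param digits Decimal places (default 1).
#' @return Percentage covered.
#' @export
coverage_percent <- function(intervals, total_len, digits = 1) {
  stopifnot(total_len > 0)
  fraction_percent(union_coverage(intervals$start, intervals$end),
                   total_len, digits)
}

#' Score predicted modules against experimental modules
#'
#' An experimental module is *hit* when at least 1 bp of it overlaps any
#' prediction on the same gene/promoter; sensitivity is the hit fraction. A
#' prediction is counted *true* under `ppv_rule = "any_overlap"` when it
#' overlaps any experimental region by >= 1 bp, or under
#' `"containment_frac"` when at least `containment_min` of its length lies
#' within the union of experimental regions; PPV is the true fraction.
#'
#' @param pred Data frame of predictions: `seq_id`, `start`, `end`.
#' @param exp Data frame of experimental modules: `seq_id` (or `gene_id`),
#'   `start`, `end`.
#' @param ppv_rule `"any_overlap"` (default) or `"containment_frac"`.
#' @param containment_min Containment fraction for the second rule
#'   (default 0.5).
#' @return A list of class `EvalResult`: `n_exp`, `n_exp_hit`, `n_pred`,
#'   `n_pred_true`, `sensitivity`, `ppv` (NA when there are no
#'   predictions), `sensitivity_pct`, `ppv_pct` (half-up, 1 decimal).
#' @export
evaluate <- function(pred, exp, ppv_rule = c("any_overlap", "containment_frac"),
                     containment_min = 0.5) {
  ppv_rule <- match.arg(ppv_rule)
  exp <- normalize_intervals(exp)
  pred <- normalize_intervals(pred)
  n_exp <- nrow(exp)
  n_pred <- nrow(pred)
  pred_by <- split(seq_len(n_pred), pred$seq_id)
  exp_by <- split(seq_len(n_exp), exp$seq_id)
  hit <- vapply(seq_len(n_exp), function(i) {
    j <- pred_by[[exp$seq_id[i]]]
    overlap_with_set(exp$start[i], exp$end[i], pred$start[j], pred$end[j]) > 0
  }, TRUE)
  true_pred <- vapply(seq_len(n_pred), function(i) {
    j <- exp_by[[pred$seq_id[i]]]
    ov <- overlap_with_set(pred$start[i], pred$end[i], exp$start[j], exp$end[j])
    if (ppv_rule == "any_overlap") {
      ov > 0
    } else {
      # containment against the union, so nested experimental regions are
      # not double counted
      if (length(j) == 0L) return(FALSE)
      cov <- union_overlap(pred$start[i], pred$end[i], exp$start[j], exp$end[j])
      cov >= containment_min * (pred$end[i] - pred$start[i])
    }
  }, TRUE)
  res <- list(
    n_exp = n_exp, n_exp_hit = sum(hit),
    n_pred = n_pred, n_pred_true = sum(true_pred),
    sensitivity = if (n_exp > 0) sum(hit) / n_exp else NA_real_,
    ppv = if (n_pred > 0) sum(true_pred) / n_pred else NA_real_)
  res$sensitivity_pct <- if (n_exp > 0)
    fraction_percent(res$n_exp_hit, n_exp) else NA_real_
  res$ppv_pct <- if (n_pred > 0)
    fraction_percent(res$n_pred_true, n_pred) else NA_real_
  structure(res, class = "EvalResult")
}

# overlap of one interval with the union of a set
union_overlap <- function(s, e, set_s, set_e) {
  cs <- pmax(s, set_s)
  ce <- pmin(e, set_e)
  keep <- cs < ce
  if (!any(keep)) return(0L)
  union_coverage(cs[keep], ce[keep])
}

normalize_intervals <- function(x) {
  if (is.null(x) || nrow(x) == 0L) {
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  if (is.null(x$seq_id) && !is.null(x$gene_id)) x$seq_id <- x$gene_id
  stopifnot(!is.null(x$seq_id), !is.null(x$start), !is.null(x$end))
  if (any(x$end <= x$start)) stop("intervals must satisfy end > start",
                                  call. = FALSE)
  x[, c("seq_id", "start", "end")]
}

#' @export
print.EvalResult <- function(x, ...) {
  cat(sprintf("sensitivity: %d/%d (%s%%)\n", x$n_exp_hit, x$n_exp,
              format(x$sensitivity_pct)))
  if (is.na(x$ppv)) {
    cat("ppv: undefined (no predictions)\n")
  } else {
    cat(sprintf("ppv: %d/%d (%s%%)\n", x$n_pred_true, x$n_pred,
                format(x$ppv_pct)))
  }
  invisible(x)
}

#' Restrict experimental modules to a size range
#'
#' Keeps modules whose length is within `[lo, hi]` bp inclusive. The study
#' default (27-580 bp) is the size range of the predicted modules, used to
#' exclude very long, poorly delimited experimental regions from
#' sensitivity estimates.
#'
#' @param exp Data frame with `start`, `end`.
#' @param lo,hi Inclusive length bounds in bp.
#' @return The filtered data frame.
#' @export
size_filter <- function(exp, lo = 27L, hi = 580L) {
  len <- exp$end - exp$start
  out <- exp[len >= lo & len <= hi, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Random-placement significance simulation
#'
#' Re-places every predicted module uniformly at random within its
#' promoter (`start ~ Uniform{0, ..., L - len}`), keeping the number and
#' lengths of modules per gene fixed, and re-runs [evaluate()]; repeated
#' `n_reps` times. Simulated modules within a gene may overlap each other.
#' Empirical p-values are the add-one-smoothed fractions of replicates with
#' a metric at least as large as observed.
#'
#' @param pred Data frame of predictions: `seq_id`, `start`, `end`.
#' @param exp Data frame of experimental modules.
#' @param promoter_lens Named vector of promoter lengths (names = seq ids);
#'   every prediction must fit its promoter.
#' @param n_reps Number of replicates (study default 10000).
#' @param seed Integer seed.
#' @param ppv_rule Passed to [evaluate()].
#' @return List with `observed` (the `EvalResult`), `mean_sens`, `sd_sens`,
#'   `mean_ppv`, `sd_ppv`, `p_sens`, `p_ppv`, `n_reps`.
#' @export
placement_simulation <- function(pred, exp, promoter_lens, n_reps = 10000L,
                                 seed = 1L,
                                 ppv_rule = c("any_overlap",
                                              "containment_frac")) {
  ppv_rule <- match.arg(ppv_rule)
  pred <- normalize_intervals(pred)
  exp <- normalize_intervals(exp)
  if (!all(pred$seq_id %in% names(promoter_lens))) {
    stop("missing promoter length for some predictions", call. = FALSE)
  }
  lens <- pred$end - pred$start
  L <- promoter_lens[pred$seq_id]
  if (any(lens > L)) stop("predicted module longer than its promoter",
                          call. = FALSE)
  observed <- evaluate(pred, exp, ppv_rule)
  sens <- numeric(n_reps)
  ppv <- numeric(n_reps)
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      new_start <- floor(stats::runif(nrow(pred)) * (L - lens + 1))
      sim <- data.frame(seq_id = pred$seq_id, start = new_start,
                        end = new_start + lens, stringsAsFactors = FALSE)
      ev <- evaluate(sim, exp, ppv_rule)
      sens[r] <- ev$sensitivity
      ppv[r] <- if (is.na(ev$ppv)) 0 else ev$ppv
    }
  })
  list(observed = observed,
       mean_sens = mean(sens), sd_sens = stats::sd(sens),
       mean_ppv = mean(ppv), sd_ppv = stats::sd(ppv),
       p_sens = (sum(sens >= observed$sensitivity) + 1) / (n_reps + 1),
       p_ppv = if (is.na(observed$ppv)) NA_real_ else
         (sum(ppv >= observed$ppv) + 1) / (n_reps + 1),
       n_reps = n_reps)
}
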