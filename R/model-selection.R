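# Choice of the number of Gaussian components by nested F tests, and the
# condition-comparison summaries (populations, mean distances) used to
# contrast biochemical states.

# Warm starts for a richer model, built by splitting the incumbent's
# dominant component on every trace that gains one. The zero-offset split
# reproduces the incumbent's signal exactly, so the richer fit can never
# end worse than the simpler one; shoulder splits use a small +/- 0.15 nm
# center offset (an emerging shoulder); variance splits place the children
# at the parent's -/+ f*sigma with halved widths (a broad blob that really
# is two separated modes), at f = 0.5 and 1. Raw weight is halved so the
# model's signal is nearly unchanged by the split.
split_dominant <- function(m, extra, kind) {
  for (e in seq_len(extra)) {
    j <- which.max(m["weight", ])
    c0 <- m["center", j]; s0 <- m["width", j]
    w2 <- max(m["weight", j] / 2, 1e-3)
    if (is.character(kind)) {
      f <- as.numeric(sub("variance", "", kind))
      newcol <- c(c0 + f * s0, max(s0 / 2, 0.05), w2)
      m["center", j] <- c0 - f * s0
      m["width", j] <- max(s0 / 2, 0.05)
    } else {
      newcol <- c(c0 + kind, s0, w2)
    }
    m["weight", j] <- w2
    m <- cbind(m, newcol)
  }
  m
}

warm_starts_from <- function(cur_fit, cur_spec, cand_spec) {
  up0 <- unpack_parameters(cur_fit$par, cur_spec)
  grow <- which(cand_spec$n_components > cur_spec$n_components)
  lapply(list(0, 0.15, -0.15, "variance0.5", "variance1"), function(kind) {
    up <- up0
    for (i in grow) {
      m <- up$components[[i]]
      up$components[[i]] <-
        split_dominant(m, cand_spec$n_components[i] - ncol(m), kind)
    }
    repack_parameters(up, cand_spec)
  })
}

#' Nested-model F test on residual sums of squares
#'
#' F = ((rss1 - rss2) / (p2 - p1)) / (rss2 / (n - p2)), with the upper-tail
#' p value from the F(p2 - p1, n - p2) distribution. When the richer model
#' fits worse than the simpler one (an optimizer-failure signal), F is
#' clamped to 0 with p = 1 and a warning.
#'
#' @param rss_simple,p_simple Weighted RSS and identifiable parameter
#'   count of the simpler model.
#' @param rss_complex,p_complex Same for the richer (nested) model.
#' @param n Number of data points.
#' @param tolerance Slack allowed on `rss_complex <= rss_simple`, and the
#'   smallest RSS reduction treated as a real improvement: a difference
#'   within it (numerical dust, e.g. two essentially perfect fits of
#'   noiseless data) yields F = 0, p = 1.
#' @return Object of class `f_test_record`.
#' @export
f_test <- function(rss_simple, p_simple, rss_complex, p_complex, n,
                   tolerance = sqrt(.Machine$double.eps) *
                     max(rss_simple, 1)) {
  stopifnot(rss_simple >= 0, rss_complex >= 0)
  if (p_complex <= p_simple)
    stop("the complex model must have more parameters than the simple one")
  if (n <= p_complex)
    stop("n must exceed the complex model's parameter count")
  if (rss_complex > rss_simple) {
    warning("richer model has larger RSS than the simpler one",
            if (rss_complex > rss_simple + tolerance)
              " beyond tolerance (optimizer failure?)" else "",
            "; F clamped to 0")
    f_stat <- 0
    p_value <- 1
  } else if (rss_simple - rss_complex <= tolerance) {
    f_stat <- 0
    p_value <- 1
  } else {
    f_stat <- ((rss_simple - rss_complex) / (p_complex - p_simple)) /
      (rss_complex / (n - p_complex))
    p_value <- pf(f_stat, p_complex - p_simple, n - p_complex,
                  lower.tail = FALSE)
  }
  structure(list(rss_simple = rss_simple, rss_complex = rss_complex,
                 p_simple = p_simple, p_complex = p_complex, n = n,
                 f_stat = f_stat, p_value = p_value),
            class = "f_test_record")
}

#' @export
print.f_test_record <- function(x, ...) {
  cat(sprintf("<f_test_record> F(%d, %d) = %.4g, p = %.4g\n",
              x$p_complex - x$p_simple, x$n - x$p_complex,
              x$f_stat, x$p_value))
  invisible(x)
}

#' Select the number of Gaussian components by forward F tests
#'
#' Starting from one component per trace, the group is refit with one
#' extra component on every eligible trace and the pooled (group-level)
#' F test compares the two fits. If p < alpha the extra component is
#' accepted; in multi-trace groups it is granted only to the trace whose
#' own RSS improved the most in the candidate fit, and the group is refit
#' with that configuration. Selection stops at the first rejection or when
#' every trace has `max_components`.
#'
#' Each candidate fit is warm-started from the incumbent model (its
#' dominant component split into two, offset by +/- 0.15 nm) in addition
#' to the usual multi-start set, so the richer model never fits worse than
#' the simpler one merely for want of a good starting point.
#'
#' @param traces List of [dipolar_trace()] (one fit group).
#' @param max_components Largest number of components per trace.
#' @param alpha Significance level of the F test.
#' @param ... Further arguments passed to [fit_spec()] (`n_starts`,
#'   `seed`, `bounds`, `share_background`, ...).
#' @return Object of class `model_selection_result` with elements
#'   `chosen` (the accepted `global_fit_result`), `ladder` (list of
#'   `f_test_record`), `alpha` and `n_components_final` (named per
#'   condition).
#' @export
select_components <- function(traces, max_components = 4L, alpha = 0.05,
                              ...) {
  cur_spec <- fit_spec(traces, n_components = 1L, ...)
  cur_fit <- global_fit(cur_spec)
  ids <- cur_spec$conditions
  ntr <- length(ids)
  cur_n <- setNames(rep(1L, ntr), ids)
  ladder <- list()
  refit_with_warm_starts <- function(n_comp) {
    sp <- fit_spec(traces, n_components = unname(n_comp), ...)
    sp$extra_starts <- warm_starts_from(cur_fit, cur_fit$spec, sp)
    global_fit(sp)
  }
  repeat {
    elig <- cur_n < max_components
    if (!any(elig)) break
    cand_n <- cur_n + as.integer(elig)
    cand_fit <- tryCatch(refit_with_warm_starts(cand_n),
                         error = function(e) e)
    if (inherits(cand_fit, "error")) {
      warning("fit failed at ", sum(cand_n),
              " total components; keeping the last successful model (",
              conditionMessage(cand_fit), ")")
      break
    }
    ft <- f_test(cur_fit$rss, cur_fit$n_params,
                 cand_fit$rss, cand_fit$n_params, cur_fit$n_points)
    ladder[[length(ladder) + 1L]] <- ft
    if (ft$p_value >= alpha) break
    if (sum(elig) == 1L) {
      cur_n <- cand_n
      cur_fit <- cand_fit
    } else {
      red <- cur_fit$rss_per_trace - cand_fit$rss_per_trace
      red[!elig] <- -Inf
      j <- names(which.max(red))
      cur_n[j] <- cur_n[j] + 1L
      step_fit <- tryCatch(refit_with_warm_starts(cur_n),
                           error = function(e) e)
      if (inherits(step_fit, "error")) {
        warning("fit failed after granting a component to '", j,
                "'; keeping the last successful model (",
                conditionMessage(step_fit), ")")
        cur_n[j] <- cur_n[j] - 1L
        break
      }
      cur_fit <- step_fit
    }
  }
  structure(list(chosen = cur_fit, ladder = ladder, alpha = alpha,
                 n_components_final = cur_n),
            class = "model_selection_result")
}

#' @export
print.model_selection_result <- function(x, ...) {
  cat("<model_selection_result> alpha = ", x$alpha, "; components: ",
      paste(names(x$n_components_final), x$n_components_final,
            sep = "=", collapse = ", "), "\n", sep = "")
  for (ft in x$ladder)
    cat(sprintf("  %d -> %d params: F = %.4g, p = %.4g (%s)\n",
                ft$p_simple, ft$p_complex, ft$f_stat, ft$p_value,
                if (ft$p_value < x$alpha) "accepted" else "rejected"))
  invisible(x)
}

#' Summarize one condition of a global fit
#'
#' Populations are the normalized component weights; the mean distance is
#' computed on the evaluated grid (so truncation at the grid edges is
#' reflected). Distances are reported in angstroms.
#'
#' @param result A `global_fit_result`.
#' @param condition_id Condition to summarize.
#' @param r_grid Distance grid (nm) for the grid-based mean.
#' @return Object of class `condition_summary` with `condition_id`,
#'   `mean_distance_A`, `depth`, `background_rate` and a `components`
#'   data frame (center_A, width_A, population).
#' @export
summarize_condition <- function(result, condition_id,
                                r_grid = default_r_grid()) {
  stopifnot(inherits(result, "global_fit_result"))
  if (!condition_id %in% result$conditions)
    stop("condition '", condition_id, "' not present in this fit")
  pt <- result$per_trace[[condition_id]]
  P <- evaluate_distribution(pt$distribution, r_grid)
  wr <- trapz_weights(r_grid)
  mean_nm <- sum(wr * r_grid * P)
  comps <- pt$distribution$components
  tab <- data.frame(
    center_A = 10 * vapply(comps, `[[`, numeric(1), "center"),
    width_A = 10 * vapply(comps, `[[`, numeric(1), "width"),
    population = vapply(comps, `[[`, numeric(1), "weight"))
  structure(list(condition_id = condition_id,
                 mean_distance_A = 10 * mean_nm,
                 depth = pt$depth,
                 background_rate = unname(result$rates[condition_id]),
                 components = tab),
            class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat("<condition_summary> ", x$condition_id, ": mean distance ",
      sprintf("%.1f", x$mean_distance_A), " A, depth ",
      format(signif(x$depth, 3)), "\n", sep = "")
  print(x$components, row.names = FALSE)
  invisible(x)
}

#' Compare component populations across conditions
#'
#' Each Gaussian component is assigned to the nearest reference state
#' (within `tolerance` angstroms of its center) and populations are
#' accumulated per state; components matching no state land in an
#' `unassigned` bucket. The shift table subtracts the first condition's
#' populations, so rows read as population gained or lost relative to it.
#'
#' @param summaries List of [summarize_condition()] outputs (>= 2 for a
#'   shift table).
#' @param reference Named numeric vector of reference state centers in
#'   angstroms, e.g. `c(nucleotide_bound = 25, HES_like = 45)`.
#' @param tolerance Maximum center-to-reference distance (A) for
#'   assignment.
#' @return List with `populations` and `shifts` data frames (one row per
#'   condition; columns per state plus `unassigned`).
#' @export
compare_conditions <- function(summaries, reference, tolerance = 3) {
  if (length(summaries) < 1L) stop("at least one summary is required")
  ok <- vapply(summaries, inherits, logical(1), "condition_summary")
  if (!all(ok)) stop("summaries must be condition_summary objects")
  if (is.null(names(reference)) || !is.numeric(reference))
    stop("reference must be a named numeric vector of state centers (A)")
  states <- names(reference)
  rows <- lapply(summaries, function(sm) {
    pops <- setNames(numeric(length(states) + 1L),
                     c(states, "unassigned"))
    assigned_to <- character(0)
    for (i in seq_len(nrow(sm$components))) {
      d <- abs(sm$components$center_A[i] - reference)
      j <- which.min(d)
      if (d[j] <= tolerance) {
        st <- states[j]
        if (st %in% assigned_to)
          warning("condition '", sm$condition_id, "': several components ",
                  "assigned to state '", st, "'; populations pooled")
        assigned_to <- c(assigned_to, st)
        pops[st] <- pops[st] + sm$components$population[i]
      } else {
        pops["unassigned"] <- pops["unassigned"] + sm$components$population[i]
      }
    }
    pops
  })
  populations <- as.data.frame(do.call(rbind, rows))
  populations <- cbind(
    condition = vapply(summaries, `[[`, character(1), "condition_id"),
    populations)
  rownames(populations) <- NULL
  shifts <- populations
  shifts[, -1L] <- sweep(as.matrix(populations[, -1L]), 2L,
                         as.numeric(populations[1L, -1L]), "-")
  list(populations = populations, shifts = shifts)
}
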