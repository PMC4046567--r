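# Bound-constrained weighted least-squares fitting of one or many dipolar
# traces, with the intermolecular background rate shared across all traces
# of a spin-label pair and every other parameter free per trace.

#' Default box bounds for fit parameters
#'
#' Centers 1.5-8 nm, widths 0.05-1.5 nm, raw component weights 0-1,
#' modulation depth 0.01-0.8, background rate 0-2 per us.
#'
#' The width floor is 2.5 distance-grid steps: it keeps every candidate
#' distribution resolvable by the 0.02 nm quadrature grid, and stops the
#' optimizer from parking delta-like components on noise Fourier modes,
#' which a grid cannot represent faithfully anyway. Spin-label distance
#' components narrower than 0.05 nm do not occur physically (rotamer
#' spread alone is broader).
#'
#' @return Named list of `c(low, high)` pairs.
#' @export
default_fit_bounds <- function() {
  list(center = c(1.5, 8.0), width = c(0.05, 1.5), weight = c(0, 1),
       depth = c(0.01, 0.8), rate = c(0, 2))
}

#' Specification of a (global) fit
#'
#' @param traces List of [dipolar_trace()] objects. They are ordered
#'   canonically by `condition_id` internally, so the order given here
#'   never affects the result.
#' @param n_components Number of Gaussian components per trace (scalar or
#'   vector along the canonical condition order).
#' @param share_background Share one background rate across all traces
#'   (requires a common `pair_id`). Default `TRUE`.
#' @param share_depth Share one modulation depth across traces. Default
#'   `FALSE`: labelling and inversion efficiency differ between samples.
#' @param bounds Named list overriding [default_fit_bounds()] entries.
#' @param n_starts Number of multi-start optimizations (>= 1). The first
#'   start is always the bound midpoints; the rest are Latin-hypercube
#'   draws seeded by `seed`.
#' @param seed Integer seed for the start draws.
#' @param tolerances List with `gradient`, `step` and `max_evaluations`.
#' @param r_grid Distance grid for the kernel quadrature (nm).
#' @param extra_starts Optional list of additional packed start vectors
#'   (clamped into the bounds), appended to the multi-start set; used by
#'   [select_components()] to warm-start each ladder rung from the
#'   incumbent model.
#' @return Object of class `fit_spec`.
#' @export
fit_spec <- function(traces, n_components = 1L, share_background = TRUE,
                     share_depth = FALSE, bounds = list(), n_starts = 20L,
                     seed = 0L,
                     tolerances = list(gradient = 1e-9, step = 1e-10,
                                       max_evaluations = 5e4),
                     r_grid = default_r_grid(), extra_starts = list()) {
  if (inherits(traces, "dipolar_trace")) traces <- list(traces)
  ok <- vapply(traces, inherits, logical(1), "dipolar_trace")
  if (length(traces) < 1L || !all(ok))
    stop("traces must be a list of dipolar_trace objects")
  ids <- vapply(traces, `[[`, character(1), "condition_id")
  if (anyDuplicated(ids))
    stop("condition_id values must be unique within a fit group")
  ord <- order(ids, method = "radix")
  traces <- traces[ord]
  ids <- ids[ord]
  if (share_background &&
      length(unique(vapply(traces, `[[`, character(1), "pair_id"))) > 1L)
    stop("shared-background fits require all traces to have the same pair_id")
  ntr <- length(traces)
  n_components <- as.integer(rep(n_components, length.out = ntr))
  if (any(n_components < 1L)) stop("n_components must be >= 1")
  b <- default_fit_bounds()
  b[names(bounds)] <- bounds
  n_starts <- as.integer(n_starts)
  if (n_starts < 1L) stop("n_starts must be >= 1")
  tol <- list(gradient = 1e-9, step = 1e-10, max_evaluations = 5e4)
  tol[names(tolerances)] <- tolerances
  spec <- structure(
    list(traces = traces, conditions = ids, n_components = n_components,
         share_background = share_background, share_depth = share_depth,
         bounds = b, n_starts = n_starts, seed = as.integer(seed),
         tolerances = tol, r_grid = r_grid, extra_starts = extra_starts),
    class = "fit_spec")
  lay <- parameter_layout(spec)
  n_points <- sum(vapply(traces, function(x) length(x$t), integer(1)))
  if (identifiable_params(spec) >= n_points)
    stop("model has as many free parameters (", identifiable_params(spec),
         ") as data points (", n_points, ")")
  spec
}

# Index layout of the packed parameter vector. Ordering (shared case):
# [shared rate] then per trace [depth, then per component
# (center, width, raw_weight)]. Unshared rates/depths slot in front of
# each trace's own block.
parameter_layout <- function(spec) {
  ntr <- length(spec$traces)
  rate_idx <- integer(ntr); depth_idx <- integer(ntr)
  comp <- vector("list", ntr)
  names_out <- character(0)
  pos <- 0L
  if (spec$share_background) {
    pos <- pos + 1L
    rate_idx[] <- pos
    names_out <- c(names_out, "rate")
  }
  if (spec$share_depth) {
    pos <- pos + 1L
    depth_idx[] <- pos
    names_out <- c(names_out, "depth")
  }
  for (i in seq_len(ntr)) {
    id <- spec$conditions[i]
    if (!spec$share_background) {
      pos <- pos + 1L
      rate_idx[i] <- pos
      names_out <- c(names_out, paste0("rate[", id, "]"))
    }
    if (!spec$share_depth) {
      pos <- pos + 1L
      depth_idx[i] <- pos
      names_out <- c(names_out, paste0("depth[", id, "]"))
    }
    k <- spec$n_components[i]
    m <- matrix(pos + seq_len(3L * k), nrow = 3L)
    rownames(m) <- c("center", "width", "weight")
    comp[[i]] <- m
    pos <- pos + 3L * k
    names_out <- c(names_out,
                   as.vector(vapply(seq_len(k), function(j)
                     paste0(c("center", "width", "weight"),
                            "[", id, ".", j, "]"), character(3))))
  }
  list(rate_idx = rate_idx, depth_idx = depth_idx, comp = comp,
       n_par = pos, names = names_out)
}

identifiable_params <- function(spec) {
  parameter_layout(spec)$n_par - length(spec$traces)
}

#' Pack a fit specification into a parameter vector and bounds
#'
#' Deterministic ordering: shared background rate first (when shared),
#' then per trace the modulation depth followed by
#' (center, width, raw_weight) triples per component. Raw weights are
#' mapped to normalized populations w_i = raw_i / sum(raw_j) whenever the
#' model is evaluated, which leaves one redundant degree of freedom per
#' trace; identifiable parameter counts subtract it.
#'
#' @param spec A [fit_spec()].
#' @return List with `lower`, `upper`, `start` (bound midpoints), `names`
#'   and `n_par`.
#' @export
pack_parameters <- function(spec) {
  stopifnot(inherits(spec, "fit_spec"))
  lay <- parameter_layout(spec)
  lower <- numeric(lay$n_par); upper <- numeric(lay$n_par)
  b <- spec$bounds
  lower[lay$rate_idx] <- b$rate[1L]; upper[lay$rate_idx] <- b$rate[2L]
  lower[lay$depth_idx] <- b$depth[1L]; upper[lay$depth_idx] <- b$depth[2L]
  for (m in lay$comp) {
    lower[m["center", ]] <- b$center[1L]; upper[m["center", ]] <- b$center[2L]
    lower[m["width", ]] <- b$width[1L]; upper[m["width", ]] <- b$width[2L]
    lower[m["weight", ]] <- b$weight[1L]; upper[m["weight", ]] <- b$weight[2L]
  }
  list(lower = lower, upper = upper, start = (lower + upper) / 2,
       names = lay$names, n_par = lay$n_par, layout = lay)
}

#' Unpack a parameter vector
#'
#' Inverse of the packing used by [pack_parameters()]: returns the
#' structured parameters along the canonical condition order.
#'
#' @param params Packed numeric vector.
#' @param spec A [fit_spec()].
#' @return List with `rates` (named, length 1 if shared), `depths` (named)
#'   and `components` (per condition, a matrix with rows center, width,
#'   raw weight).
#' @export
unpack_parameters <- function(params, spec) {
  lay <- parameter_layout(spec)
  if (length(params) != lay$n_par)
    stop("parameter vector has length ", length(params),
         " but the layout requires ", lay$n_par)
  ids <- spec$conditions
  rates <- params[unique(lay$rate_idx)]
  names(rates) <- if (spec$share_background) "shared" else ids
  depths <- params[unique(lay$depth_idx)]
  names(depths) <- if (spec$share_depth) "shared" else ids
  comps <- lapply(seq_along(ids), function(i) {
    m <- lay$comp[[i]]
    out <- matrix(params[m], nrow = 3L,
                  dimnames = list(c("center", "width", "weight"), NULL))
    out
  })
  names(comps) <- ids
  list(rates = rates, depths = depths, components = comps)
}

#' Repack structured parameters into a vector
#'
#' @param unpacked Output of [unpack_parameters()].
#' @param spec The matching [fit_spec()].
#' @return Packed numeric vector.
#' @export
repack_parameters <- function(unpacked, spec) {
  lay <- parameter_layout(spec)
  x <- numeric(lay$n_par)
  x[unique(lay$rate_idx)] <- unpacked$rates
  x[unique(lay$depth_idx)] <- unpacked$depths
  for (i in seq_along(lay$comp)) x[lay$comp[[i]]] <- unpacked$components[[i]]
  x
}

# Pre-computed quantities for fast residual evaluation.
build_fit_context <- function(spec) {
  lay <- parameter_layout(spec)
  rg <- spec$r_grid
  wr <- trapz_weights(rg)
  traces <- lapply(spec$traces, function(tr) {
    K <- kernel_matrix(tr$t, rg)
    list(t = tr$t, V = tr$V, inv_sd = 1 / tr$noise_sd,
         Kw = sweep(K, 2L, wr, "*"), n = length(tr$t))
  })
  npts <- vapply(traces, `[[`, integer(1), "n")
  list(layout = lay, traces = traces, r_grid = rg, wr = wr,
       offsets = c(0L, cumsum(npts)), n_points = sum(npts))
}

fit_residuals_ctx <- function(x, ctx) {
  lay <- ctx$layout
  rg <- ctx$r_grid; wr <- ctx$wr
  out <- numeric(ctx$n_points)
  for (i in seq_along(ctx$traces)) {
    tr <- ctx$traces[[i]]
    rate <- x[lay$rate_idx[i]]
    depth <- x[lay$depth_idx[i]]
    m <- lay$comp[[i]]
    cc <- x[m["center", ]]; ww <- x[m["width", ]]; aa <- x[m["weight", ]]
    sa <- sum(aa)
    w <- if (sa > 0) aa / sa else rep(1 / length(aa), length(aa))
    P <- numeric(length(rg))
    for (j in seq_along(cc)) P <- P + w[j] * dnorm(rg, cc[j], ww[j])
    den <- sum(wr * P)
    Fv <- (tr$Kw %*% P) / den
    V <- ((1 - depth) + depth * Fv) * exp(-rate * tr$t)
    out[(ctx$offsets[i] + 1L):ctx$offsets[i + 1L]] <-
      (tr$V - V) * tr$inv_sd
  }
  out
}

#' Weighted residual vector of a fit specification
#'
#' Concatenation over traces (canonical condition order) of
#' (V_data - V_model) / noise_sd, with the model evaluated from the packed
#' parameter vector.
#'
#' @param params Packed parameter vector (see [pack_parameters()]).
#' @param spec A [fit_spec()].
#' @return Numeric residual vector of length `sum(points per trace)`.
#' @export
fit_residuals <- function(params, spec) {
  stopifnot(inherits(spec, "fit_spec"))
  res <- fit_residuals_ctx(params, build_fit_context(spec))
  if (any(!is.finite(res)))
    stop("fit failure: model evaluation produced non-finite values")
  res
}

with_preserved_rng <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  force(code)
}

#' Global fit of a group of dipolar traces
#'
#' Runs `n_starts` bound-constrained Levenberg-Marquardt least-squares
#' minimizations (minpack.lm) of the weighted residuals. The first start
#' uses the bound midpoints; the remaining starts are Latin-hypercube
#' draws within the bounds, seeded by `spec$seed`, so the whole procedure
#' is deterministic given (data, spec, seed). Because the objective is
#' separable across traces except for shared parameters, a final
#' "recombined" start assembles the best per-trace parameter blocks found
#' in any start and polishes them jointly. The result with the lowest
#' weighted residual sum of squares is returned, with components sorted by
#' center (ties by width) and populations renormalized to sum to one.
#'
#' @param spec A [fit_spec()].
#' @return Object of class `global_fit_result` with elements `per_trace`
#'   (per condition: `distribution`, `depth`), `shared_rate` or `rates`,
#'   `rss`, `rss_per_trace`, `n_points`, `n_params` (identifiable),
#'   `per_point_residuals`, `uncertainties`, `start_diagnostics`, `seed`,
#'   `par` (packed optimum) and `par_names`.
#' @export
global_fit <- function(spec) {
  stopifnot(inherits(spec, "fit_spec"))
  ctx <- build_fit_context(spec)
  pk <- pack_parameters(spec)
  n_par <- pk$n_par
  starts <- matrix(pk$start, nrow = 1L)
  if (spec$n_starts > 1L) {
    u <- with_preserved_rng({
      set.seed(spec$seed)
      lhs::randomLHS(spec$n_starts - 1L, n_par)
    })
    extra <- sweep(sweep(u, 2L, pk$upper - pk$lower, "*"),
                   2L, pk$lower, "+")
    starts <- rbind(starts, extra)
  }
  labels <- as.character(seq_len(nrow(starts)))
  # Data-driven starts for one-component-per-trace fits: the background
  # rate and modulation depth are read off the tail of each decay (where
  # the form factor has decayed, V ~ (1 - lambda) exp(-k t), so the tail
  # log-slope estimates k and the tail intercept 1 - lambda), and a short
  # scan of candidate centers covers the distance range. Richer models
  # inherit these through the component-ladder starts below.
  if (all(spec$n_components == 1L)) {
    tail_est <- lapply(spec$traces, function(tr) {
      n <- length(tr$t)
      ix <- seq.int(max(1L, n - floor(n / 3) + 1L), n)
      ok <- ix[tr$V[ix] > 0]
      if (length(ok) < 8L) return(list(rate = 0.1, depth = 0.3))
      cf <- stats::coef(stats::lm(log(tr$V[ok]) ~ tr$t[ok]))
      list(rate = min(max(-cf[[2L]], spec$bounds$rate[1L] + 1e-6),
                      spec$bounds$rate[2L]),
           depth = min(max(1 - exp(cf[[1L]]), spec$bounds$depth[1L]),
                       spec$bounds$depth[2L]))
    })
    lay0 <- parameter_layout(spec)
    for (c0 in c(2.0, 2.75, 3.5, 4.25, 5.0, 6.0)) {
      x <- pk$start
      for (i in seq_along(spec$traces)) {
        x[lay0$rate_idx[i]] <- tail_est[[i]]$rate
        x[lay0$depth_idx[i]] <- tail_est[[i]]$depth
        x[lay0$comp[[i]]["center", 1L]] <- c0
        x[lay0$comp[[i]]["width", 1L]] <- 0.3
        x[lay0$comp[[i]]["weight", 1L]] <- 0.5
      }
      if (spec$share_background)
        x[lay0$rate_idx[1L]] <- stats::median(
          vapply(tail_est, `[[`, numeric(1), "rate"))
      if (spec$share_depth)
        x[lay0$depth_idx[1L]] <- stats::median(
          vapply(tail_est, `[[`, numeric(1), "depth"))
      starts <- rbind(starts, pmin(pmax(x, pk$lower), pk$upper))
      labels <- c(labels, "tail")
    }
  }
  # Hierarchical start for multi-trace groups: fit every trace on its own
  # (cheap, low-dimensional) and assemble a joint start from the per-trace
  # solutions with the median background rate. Global analysis only
  # sharpens shared parameters; the per-trace basins are best found
  # per trace.
  if (length(spec$traces) > 1L) {
    hier <- tryCatch({
      subs <- lapply(seq_along(spec$traces), function(i) {
        ssp <- fit_spec(spec$traces[i],
                        n_components = spec$n_components[i],
                        share_background = spec$share_background,
                        share_depth = FALSE, bounds = spec$bounds,
                        n_starts = spec$n_starts, seed = spec$seed,
                        tolerances = spec$tolerances, r_grid = spec$r_grid)
        list(spec = ssp, fit = global_fit(ssp))
      })
      up <- unpack_parameters(pk$start, spec)
      rates <- vapply(subs, function(s)
        unname(s$fit$rates[1L]), numeric(1))
      if (spec$share_background) up$rates[] <- stats::median(rates)
      else up$rates[] <- rates
      for (i in seq_along(subs)) {
        sup <- unpack_parameters(subs[[i]]$fit$par, subs[[i]]$spec)
        if (!spec$share_depth) up$depths[i] <- sup$depths
        up$components[[i]] <- sup$components[[1L]]
      }
      if (spec$share_depth)
        up$depths[] <- stats::median(vapply(subs, function(s)
          unname(unpack_parameters(s$fit$par, s$spec)$depths[1L]),
          numeric(1)))
      repack_parameters(up, spec)
    }, error = function(e) NULL)
    if (!is.null(hier)) {
      starts <- rbind(starts, pmin(pmax(hier, pk$lower), pk$upper))
      labels <- c(labels, "hierarchical")
    }
  }
  # Component-ladder start: unless the caller already supplies warm starts
  # (as the selection ladder does), fit the nested model with one fewer
  # component per trace and split its dominant component. This makes the
  # best k-component RSS structurally no worse than the best (k-1)-RSS.
  warm <- spec$extra_starts
  if (length(warm) == 0L && any(spec$n_components > 1L)) {
    ladder_starts <- tryCatch({
      rsp <- fit_spec(spec$traces,
                      n_components = pmax(spec$n_components - 1L, 1L),
                      share_background = spec$share_background,
                      share_depth = spec$share_depth, bounds = spec$bounds,
                      n_starts = spec$n_starts, seed = spec$seed,
                      tolerances = spec$tolerances, r_grid = spec$r_grid)
      warm_starts_from(global_fit(rsp), rsp, spec)
    }, error = function(e) NULL)
    if (!is.null(ladder_starts)) warm <- ladder_starts
  }
  for (xs in warm) {
    if (length(xs) != n_par)
      stop("extra start has length ", length(xs), ", expected ", n_par)
    starts <- rbind(starts, pmin(pmax(xs, pk$lower), pk$upper))
    labels <- c(labels, "warm")
  }
  ctrl <- minpack.lm::nls.lm.control(
    ftol = 1e-14, ptol = spec$tolerances$step,
    gtol = spec$tolerances$gradient,
    maxfev = spec$tolerances$max_evaluations, maxiter = 1000L)
  fn <- function(p) fit_residuals_ctx(p, ctx)
  ntr <- length(spec$traces)
  trace_rss <- function(fvec) vapply(seq_len(ntr), function(i)
    sum(fvec[(ctx$offsets[i] + 1L):ctx$offsets[i + 1L]]^2), numeric(1))
  n_total <- nrow(starts)
  objs <- rep(NA_real_, n_total)
  infos <- rep(NA_integer_, n_total)
  msgs <- character(n_total)
  sols <- vector("list", n_total)
  best <- NULL
  run_start <- function(par0, s) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = par0, lower = pk$lower,
                         upper = pk$upper, fn = fn, control = ctrl),
      error = function(e) e)
    if (inherits(res, "error")) {
      msgs[s] <<- conditionMessage(res)
      return(invisible(NULL))
    }
    dev <- sum(res$fvec^2)
    objs[s] <<- dev
    infos[s] <<- res$info
    msgs[s] <<- res$message
    sols[[s]] <<- list(par = res$par, rss_i = trace_rss(res$fvec))
    if (is.finite(dev) && (is.null(best) || dev < best$dev))
      best <<- list(dev = dev, par = res$par, fvec = res$fvec, start = s)
    invisible(NULL)
  }
  for (s in seq_len(n_total)) run_start(starts[s, ], s)
  # The objective is separable across traces except for shared parameters:
  # recombine the best per-trace blocks found in any start and polish once
  # more, so one badly started trace cannot spoil a whole start.
  if (ntr > 1L && !is.null(best)) {
    lay <- parameter_layout(spec)
    x_rec <- best$par
    for (i in seq_len(ntr)) {
      ri <- vapply(sols, function(sl)
        if (is.null(sl)) Inf else sl$rss_i[i], numeric(1))
      s_i <- which.min(ri)
      if (is.finite(ri[s_i])) {
        idx <- c(lay$comp[[i]])
        if (!spec$share_depth) idx <- c(lay$depth_idx[i], idx)
        if (!spec$share_background) idx <- c(lay$rate_idx[i], idx)
        x_rec[idx] <- sols[[s_i]]$par[idx]
      }
    }
    s <- n_total + 1L
    objs <- c(objs, NA_real_); infos <- c(infos, NA_integer_)
    msgs <- c(msgs, ""); sols <- c(sols, list(NULL))
    labels <- c(labels, "recombined")
    n_total <- s
    run_start(x_rec, s)
  }
  diagnostics <- data.frame(start = labels,
                            objective = objs, info = infos,
                            message = msgs, stringsAsFactors = FALSE)
  if (is.null(best)) {
    err <- simpleError("fit failure: no start converged to a finite objective")
    err$start_diagnostics <- diagnostics
    stop(err)
  }

  up <- unpack_parameters(best$par, spec)
  ids <- spec$conditions
  per_trace <- vector("list", length(ids))
  names(per_trace) <- ids
  for (i in seq_along(ids)) {
    m <- up$components[[i]]
    aa <- m["weight", ]
    w <- if (sum(aa) > 0) aa / sum(aa) else rep(1 / ncol(m), ncol(m))
    ord <- order(m["center", ], m["width", ])
    comps <- lapply(ord, function(j)
      gaussian_component(m["center", j], m["width", j], max(w[j], 0)))
    per_trace[[i]] <- list(
      distribution = distance_distribution(comps),
      depth = unname(if (spec$share_depth) up$depths else up$depths[i]))
  }
  npts <- vapply(ctx$traces, `[[`, integer(1), "n")
  rss_per_trace <- vapply(seq_along(ids), function(i)
    sum(best$fvec[(ctx$offsets[i] + 1L):ctx$offsets[i + 1L]]^2), numeric(1))
  names(rss_per_trace) <- ids
  result <- structure(list(
    per_trace = per_trace,
    shared_rate = if (spec$share_background) unname(up$rates) else NULL,
    rates = if (spec$share_background)
      setNames(rep(unname(up$rates), length(ids)), ids)
      else up$rates,
    rss = best$dev,
    rss_per_trace = rss_per_trace,
    n_points = ctx$n_points,
    n_params = identifiable_params(spec),
    per_point_residuals = best$fvec,
    start_diagnostics = diagnostics,
    selected_start = best$start,
    seed = spec$seed,
    par = best$par,
    par_names = pk$names,
    conditions = ids,
    spec = spec), class = "global_fit_result")
  result$uncertainties <- profile_uncertainty(result, spec)
  result
}

#' @export
print.global_fit_result <- function(x, ...) {
  cat("<global_fit_result> ", length(x$conditions), " trace(s), rss = ",
      format(signif(x$rss, 6)), ", ", x$n_params, " free parameters / ",
      x$n_points, " points\n", sep = "")
  if (!is.null(x$shared_rate))
    cat("  shared background rate: ", format(signif(x$shared_rate, 4)),
        " /us\n", sep = "")
  for (id in x$conditions) {
    pt <- x$per_trace[[id]]
    cat("  ", id, ": depth ", format(signif(pt$depth, 3)), "; centers (nm) ",
        paste(signif(vapply(pt$distribution$components, `[[`, numeric(1),
                            "center"), 4), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Standard errors of the fitted parameters
#'
#' Linearized covariance rss / (n - p) * (J' J)^-1 with the Jacobian
#' evaluated numerically at the optimum and inverted through a
#' rank-revealing singular value decomposition. Parameters pinned at a
#' bound, or lying in a null direction of J (such as the redundant raw
#' weight of a one-component trace), are flagged with `NA` errors.
#'
#' @param result A `global_fit_result`.
#' @param spec The matching [fit_spec()]; defaults to the one stored in
#'   `result`.
#' @return Data frame with columns `parameter`, `estimate`, `std_error`,
#'   `at_bound`.
#' @export
profile_uncertainty <- function(result, spec = result$spec) {
  stopifnot(inherits(result, "global_fit_result"))
  ctx <- build_fit_context(spec)
  pk <- pack_parameters(spec)
  x0 <- result$par
  f0 <- fit_residuals_ctx(x0, ctx)
  n <- length(f0); p <- length(x0)
  J <- matrix(0, n, p)
  h <- pmax(1e-6, 1e-6 * abs(x0))
  for (j in seq_len(p)) {
    xp <- x0; xm <- x0
    xp[j] <- min(x0[j] + h[j], pk$upper[j])
    xm[j] <- max(x0[j] - h[j], pk$lower[j])
    dj <- xp[j] - xm[j]
    J[, j] <- if (dj > 0)
      (fit_residuals_ctx(xp, ctx) - fit_residuals_ctx(xm, ctx)) / dj
      else 0
  }
  dof <- n - result$n_params
  s2 <- result$rss / max(dof, 1L)
  sv <- svd(J)
  tol <- max(dim(J)) * .Machine$double.eps * max(sv$d, 0)
  keep <- sv$d > tol
  se <- sqrt(s2 * rowSums(sweep(sv$v[, keep, drop = FALSE]^2, 2L,
                                sv$d[keep]^2, "/")))
  null_mass <- if (any(!keep))
    rowSums(sv$v[, !keep, drop = FALSE]^2) else numeric(p)
  btol <- 1e-8 * (pk$upper - pk$lower)
  at_bound <- (x0 - pk$lower) < btol | (pk$upper - x0) < btol
  se[at_bound | null_mass > 0.5] <- NA_real_
  data.frame(parameter = pk$names, estimate = x0, std_error = se,
             at_bound = at_bound, stringsAsFactors = FALSE)
}
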