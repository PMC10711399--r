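#' Logarithmic concentration grid
#'
#' @param from,to grid limits (same units), both > 0.
#' @param points_per_decade grid density (default 12).
#' @return Increasing numeric vector including both endpoints.
#' @export
log_grid <- function(from, to, points_per_decade = 12) {
  stopifnot(from > 0, to > from, points_per_decade >= 1)
  decades <- log10(to / from)
  n <- max(1L, round(decades * points_per_decade))
  10 ^ seq(log10(from), log10(to), length.out = n + 1)
}

#' Default substrate grid: 0.1 to 100 uM, log-spaced, 12 points/decade
#' @return Numeric vector, M.
#' @export
default_s_grid <- function() log_grid(1e-7, 1e-4, 12)

#' Default inhibitor grid: 0 plus 0.01 to 100 uM log-spaced
#' @return Numeric vector, M.
#' @export
default_i_grid <- function() c(0, log_grid(1e-8, 1e-4, 12))

#' Velocity and inhibition-degree table
#'
#' Computes initial velocities on the outer product of a substrate and an
#' inhibitor grid and the inhibition degree, defined as the ratio of the
#' inhibited to the uninhibited velocity at the same substrate
#' concentration.  A degree below 1 means inhibition; above 1 means
#' activation-by-inhibition.
#'
#' @param variant one of [scheme_variants()].
#' @param params an [exosite_params()] set.
#' @param S_grid increasing vector of substrate concentrations, M (> 0).
#' @param I_grid increasing vector of inhibitor concentrations, M; must
#'   include 0 (otherwise the degree is undefined and an error is
#'   signalled).
#' @param engine `"steady-state"` (exact linear reduction, default) or
#'   `"ode"` (progress-curve integration; much slower).
#' @param thermo_correct passed to [build_scheme()].
#' @return Data frame of class `velocity_table` with columns `S`, `I`,
#'   `v` (M/s), `degree`; one row per (S, I) pair, S varying fastest.
#' @export
#' @examples
#' tab <- velocity_grid("base", with_keq(default_params(), 0),
#'                      S_grid = log_grid(1e-7, 1e-4, 3),
#'                      I_grid = c(0, log_grid(1e-6, 1e-4, 3)))
#' max(tab$degree)  # never exceeds 1 when Keq = 0
velocity_grid <- function(variant, params,
                          S_grid = default_s_grid(),
                          I_grid = default_i_grid(),
                          engine = c("steady-state", "ode"),
                          thermo_correct = TRUE) {
  engine <- match.arg(engine)
  stopifnot(length(S_grid) >= 1, length(I_grid) >= 1)
  if (any(S_grid <= 0)) stop("S grid values must be > 0", call. = FALSE)
  if (is.unsorted(S_grid, strictly = TRUE) ||
      is.unsorted(I_grid, strictly = TRUE))
    stop("grids must be strictly increasing", call. = FALSE)
  if (!any(I_grid == 0))
    stop("I grid must include 0: the inhibition degree is undefined without",
         " the uninhibited reference column", call. = FALSE)
  grid <- expand.grid(S = S_grid, I = I_grid, KEEP.OUT.ATTRS = FALSE)
  if (engine == "steady-state") {
    network <- build_scheme(variant, params, thermo_correct = thermo_correct)
    v <- vapply(seq_len(nrow(grid)), function(i)
      velocity_from_network(network, grid$S[i], grid$I[i], params$E_total),
      numeric(1))
  } else {
    v <- vapply(seq_len(nrow(grid)), function(i)
      velocity_ode(variant, params, grid$S[i], grid$I[i],
                   thermo_correct = thermo_correct)$v, numeric(1))
  }
  v0 <- v[grid$I == 0][match(grid$S, S_grid)]
  degree <- ifelse(v0 > 0, v / v0, ifelse(v == 0, 1, NA_real_))
  out <- data.frame(S = grid$S, I = grid$I, v = v, degree = degree)
  structure(out, class = c("velocity_table", "data.frame"),
            variant = variant, params = params, engine = engine)
}

#' @keywords internal
fit_result <- function(Vmax = NA_real_, Km = NA_real_, Kic = NA_real_,
                       Kiu = NA_real_, se = numeric(), rss = NA_real_,
                       converged = FALSE, n = NA_integer_, model = "") {
  structure(list(Vmax = Vmax, Km = Km, Kic = Kic, Kiu = Kiu, se = se,
                 rss = rss, converged = converged, n = n, model = model),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s, n = %d)\n", x$model,
              if (x$converged) "converged" else "NOT converged", x$n))
  cat(sprintf("  Vmax = %.6g M/s   Km = %.6g uM\n", x$Vmax, x$Km * 1e6))
  if (is.finite(x$Kic))
    cat(sprintf("  Kic  = %.6g uM     Kiu = %.6g uM\n",
                x$Kic * 1e6, x$Kiu * 1e6))
  if (length(x$se))
    cat("  std. errors:", paste(sprintf("%s = %.3g", names(x$se), x$se),
                                collapse = ", "), "\n")
  cat(sprintf("  residual norm = %.4g\n", sqrt(x$rss)))
  invisible(x)
}

#' Fit the Michaelis-Menten equation
#'
#' Least-squares fit of `v = Vmax * S / (Km + S)` to the uninhibited rows
#' (`I == 0`, or all rows when no `I` column is present) of a velocity
#' table.  Starting values come from the observed plateau and
#' half-saturation point, with a small multi-start over Km; uniform
#' weighting on velocities.
#'
#' @param table a [velocity_grid()] result or any data frame with `S` and
#'   `v` columns (M and M/s); needs at least 4 distinct substrate values
#'   spanning a 100-fold range.
#' @return A `kinetic_fit` (Kic and Kiu are `NA`); `converged` reports
#'   the optimizer status honestly, no exception on non-convergence.
#' @export
fit_michaelis_menten <- function(table) {
  df <- as.data.frame(table)
  if ("I" %in% names(df)) df <- df[df$I == 0, , drop = FALSE]
  stopifnot(all(c("S", "v") %in% names(df)))
  Sv <- sort(unique(df$S))
  if (length(Sv) < 4 || max(Sv) / min(Sv) < 100)
    stop("need >= 4 distinct S values spanning at least a 100-fold range",
         call. = FALSE)
  Vmax0 <- max(df$v) * 1.05
  Km0 <- Sv[which.min(abs(df$v[match(Sv, df$S)] - Vmax0 / 2))]
  best <- NULL
  for (f in c(1, 0.1, 10)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(v ~ Vmax * S / (Km + S), data = df,
                        start = list(Vmax = Vmax0, Km = Km0 * f),
                        lower = c(Vmax = 0, Km = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-30)
        best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    return(fit_result(n = nrow(df), model = "michaelis-menten"))
  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, 2), names(cf)))
  fit_result(Vmax = cf[["Vmax"]], Km = cf[["Km"]], se = se, rss = best$rss,
             converged = best$fit$convInfo$isConv, n = nrow(df),
             model = "michaelis-menten")
}

#' Global mixed-inhibition fit
#'
#' Least-squares fit of the mixed-inhibition rate law
#' `v = Vmax * S / (Km * (1 + I/Kic) + S * (1 + I/Kiu))`
#' to a full (S, I) velocity table.  Kic is the competitive component
#' (inhibitor binding to free enzyme), Kiu the uncompetitive component
#' (binding to the enzyme-substrate complex).  Velocities are weighted
#' uniformly.  Initialization is an 8-point multi-start: Km from the
#' uninhibited Michaelis-Menten fit (and 2x it), Kic and Kiu each from a
#' 2-point log grid around the median positive inhibitor concentration;
#' the lowest residual wins, ties broken by first found.  Data generated
#' from a nearly pure competitive mechanism leave Kiu weakly determined:
#' it is then reported with its (large) standard error rather than as an
#' error.
#'
#' @param table a [velocity_grid()] result or data frame with columns
#'   `S`, `I`, `v`; needs at least 4 distinct S and 4 distinct I values
#'   including `I = 0`.
#' @return A `kinetic_fit` with Vmax, Km, Kic, Kiu, standard errors,
#'   residual norm and an honest `converged` flag.
#' @export
fit_mixed_inhibition <- function(table) {
  df <- as.data.frame(table)
  stopifnot(all(c("S", "I", "v") %in% names(df)))
  Sv <- sort(unique(df$S)); Iv <- sort(unique(df$I))
  if (length(Sv) < 4)
    stop("need >= 4 distinct S values", call. = FALSE)
  if (length(Iv) < 4 || !any(Iv == 0))
    stop("need >= 4 distinct I values including I = 0", call. = FALSE)
  mm <- fit_michaelis_menten(df)
  Km0 <- if (is.finite(mm$Km) && mm$Km > 0) mm$Km else stats::median(Sv)
  Vmax0 <- if (is.finite(mm$Vmax) && mm$Vmax > 0) mm$Vmax else max(df$v)
  I_med <- stats::median(Iv[Iv > 0])
  starts <- expand.grid(Km = Km0 * c(1, 2), Kic = I_med * c(0.3, 3),
                        Kiu = I_med * c(0.3, 3))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ Vmax * S / (Km * (1 + I / Kic) + S * (1 + I / Kiu)), data = df,
        start = list(Vmax = Vmax0, Km = starts$Km[i],
                     Kic = starts$Kic[i], Kiu = starts$Kiu[i]),
        lower = rep(1e-300, 4),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss * (1 - 1e-12))
        best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    return(fit_result(n = nrow(df), model = "mixed-inhibition"))
  cf <- stats::coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, 4), names(cf)))
  fit_result(Vmax = cf[["Vmax"]], Km = cf[["Km"]], Kic = cf[["Kic"]],
             Kiu = cf[["Kiu"]], se = se, rss = best$rss,
             converged = best$fit$convInfo$isConv, n = nrow(df),
             model = "mixed-inhibition")
}

#' Dose-response profile at fixed substrate concentration
#'
#' Extracts the inhibition degree as a function of inhibitor
#' concentration at one substrate concentration and classifies its shape:
#' `"biphasic"` if the maximum degree exceeds `1 + tol` at an interior
#' grid point and the curve declines after the peak (the bell-shaped,
#' hormesis-like response), `"flat"` if the total degree range is below
#' `tol`, `"monotone-decreasing"` otherwise.  The IC50 is the inhibitor
#' concentration at which the degree crosses 0.5 on the descending limb
#' (after the peak for biphasic curves), located by monotone
#' interpolation on log concentration; it is undefined (`NA`) when the
#' degree never falls below 0.5 on the sampled range.
#'
#' @param table a [velocity_grid()] result.
#' @param S substrate concentration, M; must match a grid value.
#' @param tol degree tolerance separating genuine activation from solver
#'   noise (default 1e-3).
#' @return An object of class `dose_response_profile`: list with `S`,
#'   `I`, `degree`, `shape`, `IC50`, `peak_degree`, `peak_I`.
#' @export
dose_response_profile <- function(table, S, tol = 1e-3) {
  df <- as.data.frame(table)
  idx <- which(abs(df$S - S) <= 1e-8 * S)
  if (!length(idx))
    stop("S = ", S, " M is not present in the table", call. = FALSE)
  sub <- df[idx, ]
  sub <- sub[order(sub$I), ]
  if (nrow(sub) < 6)
    stop("need at least 6 inhibitor concentrations", call. = FALSE)
  Iv <- sub$I; deg <- sub$degree
  imax <- which.max(deg)
  interior <- imax > 1 && imax < length(deg)
  declines <- imax < length(deg) && deg[length(deg)] < deg[imax] - tol
  shape <- if (deg[imax] > 1 + tol && interior && declines) "biphasic"
  else if (max(deg) - min(deg) < tol) "flat"
  else "monotone-decreasing"
  ic50 <- NA_real_
  seg_i <- imax:length(deg)
  d <- deg[seg_i]; Is <- Iv[seg_i]
  below <- which(d <= 0.5)
  if (length(below)) {
    j <- below[1]
    if (j == 1) {
      ic50 <- Is[1]
    } else if (Is[j - 1] > 0) {
      ic50 <- 10 ^ stats::approx(x = d[c(j, j - 1)],
                                 y = log10(Is[c(j, j - 1)]), xout = 0.5)$y
    } else {
      ic50 <- stats::approx(x = d[c(j, j - 1)], y = Is[c(j, j - 1)],
                            xout = 0.5)$y
    }
  }
  structure(list(S = S, I = Iv, degree = deg, shape = shape, IC50 = ic50,
                 peak_degree = deg[imax], peak_I = Iv[imax]),
            class = "dose_response_profile")
}

#' @export
print.dose_response_profile <- function(x, ...) {
  cat(sprintf("Dose-response at S = %.4g uM: %s\n", x$S * 1e6, x$shape))
  cat(sprintf("  peak degree %.4g at I = %.4g uM; IC50 = %s uM\n",
              x$peak_degree, x$peak_I * 1e6,
              if (is.na(x$IC50)) "undefined" else sprintf("%.4g", x$IC50 * 1e6)))
  invisible(x)
}

#' Activation region of an inhibition-degree surface
#'
#' Locates the global maximum of the inhibition degree over the (S, I)
#' grid and traces the degree = 1 level set (the boundary between the
#' inhibition and activation regions) by bilinear interpolation on the
#' log-concentration grid.
#'
#' @param table a [velocity_grid()] result covering I = 0 and I > 0.
#' @param level degree level to contour (default 1).
#' @return A list with `max_degree`, `argmax` (named vector with the S
#'   and I of the maximum, M) and `boundary` (data frame of S, I points
#'   on the level set, possibly empty).
#' @export
activation_map <- function(table, level = 1) {
  df <- as.data.frame(table)
  Sv <- sort(unique(df$S)); Iv <- sort(unique(df$I))
  if (!any(df$I == 0) || !any(df$I > 0))
    stop("table must cover both I = 0 and I > 0", call. = FALSE)
  degmat <- matrix(df$degree[order(df$I, df$S)], nrow = length(Sv),
                   ncol = length(Iv))
  k <- which.max(degmat)
  arg_s <- Sv[(k - 1) %% length(Sv) + 1]
  arg_i <- Iv[(k - 1) %/% length(Sv) + 1]
  Ipos <- Iv[Iv > 0]
  cl <- grDevices::contourLines(x = log10(Sv), y = log10(Ipos),
                                z = degmat[, Iv > 0, drop = FALSE],
                                levels = level)
  boundary <- if (length(cl)) {
    do.call(rbind, lapply(seq_along(cl), function(i)
      data.frame(piece = i, S = 10 ^ cl[[i]]$x, I = 10 ^ cl[[i]]$y)))
  } else data.frame(piece = integer(), S = numeric(), I = numeric())
  list(max_degree = max(degmat), argmax = c(S = arg_s, I = arg_i),
       boundary = boundary)
}
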