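# Equilibrium binding: the 1:1 titrant-depletion isotherm used to fit Kd
# from microscale-thermophoresis (MST) dose-response curves. The labeled
# protein is held at a fixed concentration P while the unlabeled
# oligonucleotide is serially diluted; because P is not negligible relative
# to Kd, the exact depletion quadratic (not the hyperbolic approximation)
# is required.

#' Fraction of protein bound under 1:1 binding with titrant depletion
#'
#' `fb = ((c + P + Kd) - sqrt((c + P + Kd)^2 - 4 c P)) / (2 P)` — the exact
#' solution of the 1:1 mass-action equilibrium. Monotone non-decreasing in
#' the ligand concentration `c` and non-increasing in `kd`; in the dilute-
#' protein limit it reduces to `c / (c + kd)`.
#'
#' @param c Ligand concentration(s), nM (vectorized).
#' @param P Fixed protein concentration, nM (> 0).
#' @param kd Dissociation constant, nM (>= 0).
#' @return Fraction bound in `[0, 1]`.
#' @examples
#' fraction_bound(c = 100, P = 50, kd = 100)
#' @export
fraction_bound <- function(c, P, kd) {
  stopifnot(all(c >= 0), P > 0, kd >= 0)
  s <- c + P + kd
  disc <- pmax(0, s^2 - 4 * c * P)   # analytically >= 0; clamp rounding error
  pmin(1, pmax(0, (s - sqrt(disc)) / (2 * P)))
}

#' Fit the dissociation constant to a binding curve
#'
#' Unweighted least-squares fit of
#' `F(c) = f_free + (f_bound - f_free) * fraction_bound(c, P, kd)` over
#' `(kd, f_free, f_bound)`, with `kd` log-parameterized to stay positive.
#' Initial values: plateaus from the curve extremes, `kd` from the
#' concentration nearest the half-signal point. Standard errors come from
#' the local quadratic approximation of the loss (Gauss-style, via the
#' numerical Hessian at the optimum); non-convergence and unidentifiable
#' (flat) curves are flagged, never silently ignored.
#'
#' @param curve A binding-curve tibble with columns `conc_nM`, `response` and
#'   either a `protein_nM` column or attribute.
#' @param init Optional named list overriding initial values
#'   (`kd`, `f_free`, `f_bound`).
#' @return A `kd_fit` object; see [tidy.kd_fit()] / [glance.kd_fit()].
#' @examples
#' curve <- simulate_mst_curve(kd = 100, noise_sd = 0)
#' fit_kd(curve)
#' @export
fit_kd <- function(curve, init = NULL) {
  stopifnot(is.data.frame(curve), all(c("conc_nM", "response") %in% names(curve)))
  if (nrow(curve) < 6) abort("at least 6 dose points are required to fit Kd")
  if (any(curve$conc_nM <= 0)) abort("ligand concentrations must be positive")
  P <- curve$protein_nM[1] %||% attr(curve, "protein_nM")
  if (is.null(P) || !is.finite(P) || P <= 0) {
    abort("protein concentration (protein_nM) missing from the curve")
  }
  conc <- curve$conc_nM; y <- curve$response
  o <- order(conc)
  span <- y[o][length(y)] - y[o][1]      # response change from low to high conc

  # monotonicity sanity: the model is monotone in c, noisy data may not be
  fitted_dir <- sign(span)
  if (abs(span) < .Machine$double.eps * 100 || sd(y) < 1e-12) {
    return(new_kd_fit(kd = NA_real_, f_free = mean(y), f_bound = mean(y),
                      se = c(Inf, Inf, Inf), rss = sum((y - mean(y))^2),
                      converged = FALSE, curve = curve, P = P,
                      note = "flat curve: Kd unidentifiable"))
  }
  f_free0 <- init$f_free %||% y[o][1]
  f_bound0 <- init$f_bound %||% y[o][length(y)]
  half <- (f_free0 + f_bound0) / 2
  kd0 <- init$kd %||% conc[which.min(abs(y - half))]
  kd0 <- max(kd0, min(conc) / 10)

  obj <- function(par) {
    mu <- par[2] + (par[3] - par[2]) * fraction_bound(conc, P, exp(par[1]))
    sum((y - mu)^2)
  }
  par0 <- c(log(kd0), f_free0, f_bound0)
  fit1 <- optim(par0, obj, method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-14))
  fit <- optim(fit1$par, obj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14), hessian = TRUE)
  converged <- fit$convergence == 0 || fit1$convergence == 0
  par <- fit$par
  rss <- fit$value
  n <- length(y)
  sigma2 <- rss / max(1, n - 3)
  se <- rep(NA_real_, 3)
  H <- fit$hessian
  ok_h <- all(is.finite(H)) && all(diag(H) > 0)
  if (ok_h) {
    cv <- tryCatch(solve(H / 2) * sigma2, error = function(e) NULL)
    if (!is.null(cv) && all(diag(cv) >= 0)) {
      se <- sqrt(diag(cv))
      se[1] <- exp(par[1]) * se[1]     # delta method: log-kd -> kd scale
    } else {
      converged <- FALSE
    }
  } else {
    converged <- FALSE
  }
  new_kd_fit(kd = exp(par[1]), f_free = par[2], f_bound = par[3], se = se,
             rss = rss, converged = converged, curve = curve, P = P,
             note = if (fitted_dir < 0) "decreasing response curve" else NULL)
}

new_kd_fit <- function(kd, f_free, f_bound, se, rss, converged, curve, P,
                       note = NULL) {
  structure(list(kd = kd, f_free = f_free, f_bound = f_bound,
                 se_kd = se[1], se_f_free = se[2], se_f_bound = se[3],
                 rss = rss, converged = converged, n = nrow(curve),
                 protein_nM = P, data = curve, note = note),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat("<Kd fit> 1:1 depletion model, P =", x$protein_nM, "nM\n")
  cat("  Kd =", signif(x$kd, 4), "nM (SE", signif(x$se_kd, 3), ")\n")
  cat("  plateaus:", signif(x$f_free, 4), "->", signif(x$f_bound, 4),
      "  RSS =", signif(x$rss, 4), "\n")
  if (!x$converged) cat("  WARNING: fit did not converge or is unidentifiable\n")
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}

#' Tidy and glance methods for Kd fits
#'
#' @param x A `kd_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter (`term`, `estimate`,
#'   `std.error`); `glance()`: one-row fit summary.
#' @method tidy kd_fit
#' @export
tidy.kd_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kd_nM", "f_free", "f_bound"),
    estimate = c(x$kd, x$f_free, x$f_bound),
    std.error = c(x$se_kd, x$se_f_free, x$se_f_bound)
  )
}

#' @rdname tidy.kd_fit
#' @method glance kd_fit
#' @export
glance.kd_fit <- function(x, ...) {
  tibble::tibble(kd_nM = x$kd, se_kd = x$se_kd, rss = x$rss, n = x$n,
                 protein_nM = x$protein_nM, converged = x$converged)
}

#' @rdname plot_quadcoloc
#' @method autoplot kd_fit
#' @export
autoplot.kd_fit <- function(object, ...) {
  cgrid <- exp(seq(log(min(object$data$conc_nM)), log(max(object$data$conc_nM)),
                   length.out = 200))
  pred <- object$f_free + (object$f_bound - object$f_free) *
    fraction_bound(cgrid, object$protein_nM, max(object$kd, 1e-9))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$conc_nM, y = .data$response)) +
    ggplot2::geom_line(data = data.frame(conc_nM = cgrid, response = pred),
                       colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "ligand concentration (nM)", y = "response",
                  title = paste0("Kd = ", signif(object$kd, 3), " nM")) +
    ggplot2::theme_minimal()
}

#' Rank fitted affinities, censoring non-binders
#'
#' Fits whose Kd exceeds the highest tested concentration cannot be resolved
#' by the titration and are reported as censored (`> top µM`) rather than as
#' point estimates, following the reporting convention for non-binders.
#'
#' @param results Named list of `kd_fit` objects.
#' @param top_conc Highest tested ligand concentration, nM.
#' @return Tibble ranked by Kd among resolvable binders, censored fits last:
#'   `name`, `kd_nM`, `se_nM`, `censored`, `display`.
#' @export
compare_affinities <- function(results, top_conc = 20000) {
  stopifnot(is.list(results), !is.null(names(results)))
  rows <- purrr::imap(results, function(f, nm) {
    censored <- !is.finite(f$kd) || f$kd > top_conc || !f$converged
    tibble::tibble(
      name = nm, kd_nM = f$kd, se_nM = f$se_kd, censored = censored,
      display = if (censored) paste0("> ", format(top_conc / 1000), " µM")
                else paste0(signif(f$kd / 1000, 2), " ± ",
                            signif(f$se_kd / 1000, 1), " µM")
    )
  })
  dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$censored, .data$kd_nM)
}
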