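#' Dilute-solution equilibrium concentrations of an RNA triple
#'
#' Solves the mass-action equilibrium of the complexes a target mRNA (M)
#' and two miRNAs (A, B) can form from fixed strand totals. Each complex
#' `c` obeys
#' \deqn{[c] = \rho_0 \exp(-\Delta G_c / RT) \prod_s \lambda_s^{n_{s,c}}}
#' with standard state \eqn{\rho_0 = 1} M, monomer \eqn{\Delta G = 0},
#' and per-strand activities \eqn{\lambda_s} chosen so that every
#' strand-conservation equation holds. The activities are found by a
#' damped Newton iteration on \eqn{\log \lambda} with the analytic
#' Jacobian \eqn{J_{st} = \sum_c n_{s,c} n_{t,c} [c]} (symmetric positive
#' definite), falling back to per-coordinate monotone bisection sweeps
#' if Newton stalls.
#'
#' @param dg Named numeric vector of complex free energies in kcal/mol.
#'   Complex names are concatenations of single-letter strand names
#'   (e.g. `c(MA = -18, MB = -16, AB = -3, MAB = -40)`); monomers are
#'   implicit with `dG = 0` and need not be listed. `+Inf` disables a
#'   complex.
#' @param totals Named strand totals in nM (default 100 nM each of
#'   M, A, B, the convention for triplex equilibrium screening).
#' @param temperature Kelvin (default 310.15).
#' @param tol Relative tolerance on strand conservation (default 1e-10).
#' @return An `equilibrium_state`: concentrations (nM) of every species
#'   (monomers and complexes), the inputs, and the achieved residual.
#' @examples
#' # two strands, one dimer with Kd = 100 nM, totals 100 nM each
#' rt <- 1.9872e-3 * 310.15
#' dg <- rt * log(100 / 1e9) # so that rho0 * exp(-dg/RT) = 1/(100 nM)
#' eq <- equilibrium_concentrations(c(AB = dg), totals = c(A = 100, B = 100))
#' eq$concentrations[["AB"]] # 38.197 nM, the quadratic-formula dimer
#' @export
equilibrium_concentrations <- function(dg,
                                       totals = c(M = 100, A = 100, B = 100),
                                       temperature = 310.15,
                                       tol = 1e-10) {
  strands <- names(totals)
  if (is.null(strands) || any(!nzchar(strands))) abort("totals must be named")
  if (any(totals <= 0)) abort("strand totals must be > 0 nM")
  if (any(nchar(strands) != 1)) {
    abort("strand names must be single letters (complex names concatenate them)")
  }
  if (is.null(names(dg)) && length(dg)) abort("dg must be named by complex")
  if (any(is.na(dg))) abort("dg must be finite or +Inf")

  # composition matrix: n[s, c] = copies of strand s in complex c
  comp_of <- function(name) {
    letters_c <- strsplit(name, "")[[1]]
    if (!all(letters_c %in% strands)) {
      abort(sprintf("complex '%s' uses undeclared strands", name))
    }
    vapply(strands, function(s) sum(letters_c == s), integer(1))
  }
  cx_names <- union(strands, names(dg))
  nmat <- vapply(cx_names, comp_of, integer(length(strands)))
  if (is.null(dim(nmat))) nmat <- matrix(nmat, nrow = length(strands))
  rownames(nmat) <- strands
  dg_all <- setNames(rep(0, length(cx_names)), cx_names)
  dg_all[names(dg)] <- dg

  rt <- .RGAS * temperature
  log_k <- log(.RHO0_NM) - dg_all / rt # log of rho0*exp(-dG/RT) in nM units
  active <- is.finite(log_k)

  conc_at <- function(x) {
    # x = log lambda per strand
    lc <- log_k + as.vector(crossprod(nmat, x))
    z <- numeric(length(lc))
    z[active] <- exp(lc[active])
    z
  }
  resid <- function(cc) as.vector(nmat %*% cc) - unname(totals)

  x <- log(unname(totals) / .RHO0_NM) # monomer-only initial guess
  cc <- conc_at(x)
  f <- resid(cc)
  converged <- function(f) max(abs(f) / unname(totals)) <= tol

  # The conservation equations are the stationarity conditions of the
  # convex dual objective g(x) = sum_c [c](x) - sum_s T_s x_s, whose
  # Hessian is the (PSD) matrix J_st = sum_c n_sc n_tc [c]. Newton with
  # an Armijo line search on g therefore descends globally, even when a
  # single deep complex makes J nearly rank one.
  objective <- function(cc, x) sum(cc) - sum(unname(totals) * x)
  g <- objective(cc, x)
  for (iter in seq_len(500)) {
    if (converged(f)) break
    J <- nmat %*% (t(nmat) * cc)
    mu <- max(diag(J)) * 1e-14 + 1e-300
    step <- tryCatch(solve(J + diag(mu, nrow(J)), -f),
                     error = function(e) NULL)
    if (is.null(step)) break
    slope <- sum(f * step) # grad g = f
    if (!is.finite(slope) || slope >= 0) break
    lam <- 1
    improved <- FALSE
    for (h in seq_len(80)) {
      x_new <- x + lam * step
      cc_new <- conc_at(x_new)
      g_new <- objective(cc_new, x_new)
      if (is.finite(g_new) && g_new <= g + 1e-4 * lam * slope) {
        x <- x_new; cc <- cc_new; g <- g_new
        f <- resid(cc)
        improved <- TRUE
        break
      }
      lam <- lam / 2
    }
    if (!improved) break
  }

  if (!converged(f)) {
    # monotone per-coordinate bisection sweeps: each conservation equation
    # is strictly increasing in its own log-activity
    for (sweep in seq_len(2000)) {
      for (s in seq_along(x)) {
        g <- function(xs) {
          xx <- x; xx[s] <- xs
          resid(conc_at(xx))[s]
        }
        upper <- log(unname(totals)[s] / .RHO0_NM)
        root <- uniroot(g, lower = upper - 500, upper = upper,
                        tol = .Machine$double.eps^0.9)
        x[s] <- root$root
      }
      cc <- conc_at(x)
      f <- resid(cc)
      if (converged(f)) break
    }
  }
  if (!converged(f)) {
    abort(sprintf(
      "equilibrium solver did not converge; residuals: %s",
      paste(sprintf("%s=%.3g", strands, f), collapse = ", ")))
  }

  structure(
    list(
      concentrations = setNames(as.numeric(cc), cx_names),
      dg = dg_all,
      totals = totals,
      temperature = temperature,
      residual = max(abs(f) / unname(totals)),
      composition = nmat
    ),
    class = "equilibrium_state"
  )
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat("<equilibrium_state> T =", x$temperature, "K\n")
  for (nm in names(x$concentrations)) {
    cat(sprintf("  %-5s %10.4f nM   (dG = %s kcal/mol)\n", nm,
                x$concentrations[[nm]],
                format(x$dg[[nm]], digits = 4)))
  }
  cat(sprintf("  mass-conservation residual: %.2e (relative)\n", x$residual))
  invisible(x)
}

#' @export
tidy.equilibrium_state <- function(x, ...) {
  tibble(
    complex = names(x$concentrations),
    n_strands = colSums(x$composition),
    dg = as.numeric(x$dg),
    conc_nM = as.numeric(x$concentrations)
  )
}

#' @export
glance.equilibrium_state <- function(x, ...) {
  tibble(
    n_complexes = length(x$concentrations),
    triplex_nM = triplex_concentration(x),
    residual = x$residual,
    temperature = x$temperature
  )
}

#' Equilibrium concentration of the triplex species
#'
#' @param state An `equilibrium_state`.
#' @return The concentration (nM) of the three-strand complex.
#' @export
triplex_concentration <- function(state) {
  is_tri <- colSums(state$composition) == 3
  if (!any(is_tri)) return(NA_real_)
  unname(state$concentrations[which(is_tri)[1]])
}

#' Triplex equilibrium-concentration filter
#'
#' `TRUE` when the triplex equilibrium concentration (TEC) strictly
#' exceeds the threshold. With the conventional 100 nM per-species
#' totals, the default 50 nM threshold corresponds to the majority of
#' the target mRNA being sequestered in triplexes.
#'
#' @param state An `equilibrium_state` containing a three-strand complex.
#' @param threshold_nM Threshold in nM (default 50; strict `>`).
#' @return `TRUE` or `FALSE`.
#' @export
triplex_filter <- function(state, threshold_nM = 50) {
  tec <- triplex_concentration(state)
  if (is.na(tec)) abort("no three-strand complex in the equilibrium state")
  tec > threshold_nM
}
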