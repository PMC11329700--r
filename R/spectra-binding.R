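# NMR chemical-shift perturbation mapping, one-site saturation binding,
# and SRM peak-area aggregation.

#' Compute chemical shift perturbations between two peak lists
#'
#' For every residue assigned in both the free and the bound (titrated)
#' spectrum, the combined amide CSP is
#' `delta = sqrt(dH^2 + (dN/5)^2)` (ppm), the conventional 1H/15N
#' weighting that scales nitrogen shifts by 1/5. Residues present in only
#' one table — or flagged undetectable, e.g. prolines, which carry no
#' amide peak — are reported as missing, never imputed to zero.
#'
#' @param free,bound data.frames with columns `residue`, `delta_H`,
#'   `delta_N` and optional logical `detectable`.
#' @return data.frame of class `csp_profile` with columns `residue`,
#'   `delta_delta` (ppm); missing residues are listed in
#'   `attr(, "missing")`.
#' @examples
#' free <- data.frame(residue = 1:2, delta_H = c(8.1, 8.3),
#'                    delta_N = c(120, 118))
#' bound <- free; bound$delta_N[2] <- 118.5
#' compute_csp(free, bound)
#' @export
compute_csp <- function(free, bound) {
  free <- normalize_peaks(free, "free")
  bound <- normalize_peaks(bound, "bound")
  shared <- intersect(free$residue[free$detectable],
                      bound$residue[bound$detectable])
  if (length(shared) == 0) {
    stop("the free and bound tables share no detectable residues",
         call. = FALSE)
  }
  missing <- sort(unique(c(
    setdiff(free$residue, bound$residue),
    setdiff(bound$residue, free$residue),
    union(free$residue[!free$detectable], bound$residue[!bound$detectable])
  )))
  fi <- free[match(shared, free$residue), ]
  bi <- bound[match(shared, bound$residue), ]
  dH <- bi$delta_H - fi$delta_H
  dN <- bi$delta_N - fi$delta_N
  out <- data.frame(residue = shared,
                    delta_delta = sqrt(dH^2 + (dN / 5)^2))
  out <- out[order(out$residue), ]
  rownames(out) <- NULL
  attr(out, "missing") <- missing
  class(out) <- c("csp_profile", "data.frame")
  out
}

normalize_peaks <- function(tab, what) {
  stopifnot(is.data.frame(tab))
  need <- c("residue", "delta_H", "delta_N")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop(sprintf("%s table lacks columns: %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(tab$residue)) {
    stop(sprintf("%s table has duplicate residue numbers", what),
         call. = FALSE)
  }
  if (is.null(tab$detectable)) tab$detectable <- TRUE
  tab$detectable <- tab$detectable & is.finite(tab$delta_H) &
    is.finite(tab$delta_N)
  tab
}

#' Call perturbed (binding-site) residues from a CSP profile
#'
#' Residues whose CSP strictly exceeds the profile mean are called
#' perturbed ("higher than average" rule); `k_sd > 0` raises the
#' threshold to mean + k_sd standard deviations for a more conservative
#' call.
#'
#' @param profile a [compute_csp()] profile (or data.frame with `residue`
#'   and `delta_delta`).
#' @param k_sd number of profile SDs added to the mean threshold.
#' @return sorted integer vector of called residues; the threshold used
#'   is attached as `attr(, "threshold")`.
#' @export
call_perturbed_residues <- function(profile, k_sd = 0) {
  stopifnot(is.data.frame(profile),
            all(c("residue", "delta_delta") %in% names(profile)),
            nrow(profile) >= 1, k_sd >= 0)
  dd <- profile$delta_delta
  threshold <- mean(dd) + k_sd * if (k_sd > 0) sd(dd) else 0
  called <- sort(profile$residue[dd > threshold])
  attr(called, "threshold") <- threshold
  called
}

#' Fit a one-site saturation binding curve
#'
#' Least-squares fit of the single-site specific-binding model
#' `S = Bmax * L / (Kd + L)` to a concentration-signal series. The fit is
#' scale-equivariant: rescaling the signal rescales Bmax and leaves Kd
#' unchanged.
#'
#' @param curve data.frame with columns `concentration` (nM, > 0) and
#'   `signal`; replicates appear as repeated concentrations.
#' @return list of class `binding_fit`: `kd` (nM), `bmax`, `fit` (the
#'   `nls` object), and `data`.
#' @examples
#' conc <- 2^(0:7) * 5
#' fit_binding_curve(data.frame(concentration = conc,
#'                              signal = 1.8 * conc / (44 + conc)))
#' @export
fit_binding_curve <- function(curve) {
  stopifnot(is.data.frame(curve),
            all(c("concentration", "signal") %in% names(curve)))
  L <- curve$concentration
  S <- curve$signal
  stopifnot(all(L > 0), all(is.finite(S)))
  if (length(unique(L)) < 4) {
    stop("need at least 4 distinct concentrations", call. = FALSE)
  }
  bmax0 <- max(S)
  half <- bmax0 / 2
  kd0 <- L[which.min(abs(S - half))]
  lo <- c(Bmax = 0, Kd = min(L) * 1e-4)
  hi <- c(Bmax = Inf, Kd = max(L) * 1e4)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      S ~ Bmax * L / (Kd + L),
      start = list(Bmax = bmax0, Kd = max(kd0, min(L))),
      lower = lo, upper = hi,
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) stop("binding fit did not converge: ",
                             conditionMessage(e), call. = FALSE)
  )
  cf <- coef(fit)
  if (cf[["Kd"]] <= lo[["Kd"]] * 1.01 || cf[["Kd"]] >= hi[["Kd"]] * 0.99) {
    stop("fitted Kd sits at a parameter bound; the curve does not ",
         "constrain the affinity", call. = FALSE)
  }
  structure(
    list(kd = cf[["Kd"]], bmax = cf[["Bmax"]], fit = fit, data = curve),
    class = "binding_fit"
  )
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> Kd = %.3g nM, Bmax = %.3g\n", x$kd, x$bmax))
  invisible(x)
}

#' Aggregate SRM transition areas into protein abundances
#'
#' Sums each peptide's transition peak areas into a peptide total, and
#' peptide totals into a protein total; relative abundances are expressed
#' against the most abundant protein.
#'
#' @param transitions data.frame with columns `protein`, `peptide`,
#'   `transition`, `area` (>= 0).
#' @return list with `proteins` (data.frame: protein, total, ratio — the
#'   fraction of the most abundant protein's total; `NA` for zero
#'   totals), `peptides` (data.frame: protein, peptide, total), and
#'   `grand_total`.
#' @export
srm_protein_abundance <- function(transitions) {
  stopifnot(is.data.frame(transitions),
            all(c("protein", "peptide", "transition", "area") %in%
                  names(transitions)))
  if (any(transitions$area < 0)) {
    stop("negative transition peak area", call. = FALSE)
  }
  pep <- aggregate(area ~ protein + peptide, transitions, sum)
  names(pep)[names(pep) == "area"] <- "total"
  prot <- aggregate(total ~ protein, pep, sum)
  top <- max(prot$total)
  prot$ratio <- ifelse(prot$total > 0, prot$total / top, NA_real_)
  prot <- prot[order(-prot$total), ]
  rownames(prot) <- NULL
  list(proteins = prot, peptides = pep,
       grand_total = sum(transitions$area))
}
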