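# Generators for titration peak lists, saturation binding curves, and
# SRM transition tables.

#' Simulate an NMR titration series with designated binding-site residues
#'
#' Produces per-titration-point peak lists (residue, delta_H, delta_N).
#' Site residues shift saturably toward their maximal composite CSP as
#' the ligand ratio rises (fast-exchange population-weighted shifts);
#' non-site residues do not shift beyond the optional noise. Proline
#' positions carry no amide peak and are emitted with `detectable =
#' FALSE`.
#'
#' @param config a [sim_config()].
#' @param residues integer residue numbers (unique).
#' @param site_residues subset of `residues` designated as the binding
#'   site.
#' @param max_shifts maximal composite CSP (ppm) per site residue,
#'   recycled.
#' @param ratios ligand:protein molar ratios, ascending; the last is
#'   treated as saturating.
#' @param prolines residues with no amide peak.
#' @param noise_sd additive noise SD on delta_H (and 5x on delta_N), ppm.
#' @param ratio_half ratio at half-saturation of the shift.
#' @return list with `tables` (named list of peak-list data.frames, one
#'   per ratio), `ratios`, and `truth` (site residues and per-residue max
#'   composite shift).
#' @examples
#' sim <- gen_titration_series(sim_config(1), residues = 1:20,
#'                             site_residues = c(5, 6, 12))
#' call_perturbed_residues(compute_csp(sim$tables[[1]],
#'                                     sim$tables[[length(sim$tables)]]))
#' @export
gen_titration_series <- function(config, residues, site_residues,
                                 max_shifts = 0.2,
                                 ratios = c(0, 0.25, 0.5, 1, 2),
                                 prolines = integer(),
                                 noise_sd = 0,
                                 ratio_half = 0.3) {
  config <- as_sim_config(config)
  if (anyDuplicated(residues)) {
    stop("duplicate residue numbers", call. = FALSE)
  }
  stopifnot(all(site_residues %in% residues),
            all(prolines %in% residues),
            all(diff(ratios) > 0) || length(ratios) == 1,
            ratios[1] >= 0, noise_sd >= 0, ratio_half > 0,
            all(max_shifts > 0))
  site <- setdiff(site_residues, prolines)
  maxs <- setNames(rep_len(max_shifts, length(site)), site)

  with_seed(config$seed, {
    n <- length(residues)
    base_H <- runif(n, 7.5, 9.0)
    base_N <- runif(n, 110, 130)
    # split each composite shift into H and N components of equal CSP
    ang <- runif(length(site), 0.2, pi / 2 - 0.2)
    dH_max <- setNames(maxs * cos(ang), site)
    dN_max <- setNames(5 * maxs * sin(ang), site)

    tables <- lapply(ratios, function(r) {
      frac <- if (r == 0) 0 else r / (r + ratio_half)
      dH <- dN <- numeric(n)
      is_site <- residues %in% site
      dH[is_site] <- dH_max[as.character(residues[is_site])] * frac
      dN[is_site] <- dN_max[as.character(residues[is_site])] * frac
      detectable <- !(residues %in% prolines)
      tab <- data.frame(
        residue = residues,
        delta_H = base_H + dH + rnorm(n, 0, noise_sd),
        delta_N = base_N + dN + rnorm(n, 0, 5 * noise_sd),
        detectable = detectable
      )
      tab$delta_H[!detectable] <- NA_real_
      tab$delta_N[!detectable] <- NA_real_
      tab
    })
    names(tables) <- sprintf("ratio_%g", ratios)
    sat <- if (max(ratios) == 0) 0 else
      max(ratios) / (max(ratios) + ratio_half)
    list(
      tables = tables, ratios = ratios,
      truth = list(
        site_residues = sort(site),
        prolines = sort(prolines),
        max_composite_shift = maxs,
        saturation_at_end = sat
      )
    )
  })
}

#' Simulate a one-site saturation binding series
#'
#' `signal = bmax * L / (kd + L) + noise`, per concentration and
#' replicate.
#'
#' @param config a [sim_config()].
#' @param kd dissociation constant, nM (> 0).
#' @param bmax saturating signal.
#' @param concentrations ligand concentrations, nM (> 0, distinct).
#' @param noise_sd additive Gaussian noise SD, signal units.
#' @param replicates replicate measurements per concentration.
#' @return list with `curve` (data.frame: concentration, replicate,
#'   signal) and `truth` (kd, bmax).
#' @examples
#' sim <- gen_binding_curve(sim_config(1), kd = 44, bmax = 2,
#'                          concentrations = 2^(0:7) * 5)
#' fit_binding_curve(sim$curve)
#' @export
gen_binding_curve <- function(config, kd, bmax,
                              concentrations = 2^(0:7) * 5,
                              noise_sd = 0, replicates = 1) {
  config <- as_sim_config(config)
  if (kd <= 0) stop("kd must be positive", call. = FALSE)
  stopifnot(bmax > 0, all(concentrations > 0),
            !anyDuplicated(concentrations), replicates >= 1,
            noise_sd >= 0)
  with_seed(config$seed, {
    grid <- expand.grid(replicate = seq_len(replicates),
                        concentration = concentrations)
    mu <- bmax * grid$concentration / (kd + grid$concentration)
    curve <- data.frame(
      concentration = grid$concentration,
      replicate = grid$replicate,
      signal = mu + rnorm(nrow(grid), 0, noise_sd)
    )
    list(curve = curve, truth = list(kd = kd, bmax = bmax))
  })
}

#' Simulate an SRM transition table with known protein totals
#'
#' Splits each protein's total peak area across peptides and transitions
#' with random fractions that sum exactly to one, so summing transition
#' areas reconstructs every total exactly.
#'
#' @param config a [sim_config()].
#' @param protein_totals named numeric vector of total peak areas
#'   (>= 0).
#' @param n_peptides,n_transitions peptides per protein and transitions
#'   per peptide (>= 3 each, per conventional assay design).
#' @return list with `transitions` (data.frame: protein, peptide,
#'   transition, area) and `truth` (the totals).
#' @export
gen_srm_table <- function(config, protein_totals, n_peptides = 3,
                          n_transitions = 3) {
  config <- as_sim_config(config)
  stopifnot(length(protein_totals) >= 1, !is.null(names(protein_totals)),
            all(protein_totals >= 0), n_peptides >= 3, n_transitions >= 3)
  with_seed(config$seed, {
    rows <- list()
    for (prot in names(protein_totals)) {
      k <- n_peptides * n_transitions
      w <- runif(k, 0.2, 1)
      frac <- w / sum(w)
      area <- protein_totals[[prot]] * frac
      # pin the last area so the split sums exactly to the total
      area[k] <- protein_totals[[prot]] - sum(area[-k])
      rows[[prot]] <- data.frame(
        protein = prot,
        peptide = sprintf("%s_pep%02d", prot,
                          rep(seq_len(n_peptides), each = n_transitions)),
        transition = sprintf("y%d", rep(seq_len(n_transitions),
                                        times = n_peptides) + 3L),
        area = area
      )
    }
    transitions <- do.call(rbind, rows)
    rownames(transitions) <- NULL
    list(transitions = transitions, truth = list(totals = protein_totals))
  })
}
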