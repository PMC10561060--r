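#' Contour length of a tether from its residue count
#'
#' Fully extended length of an unstructured polypeptide: residues times the
#' 0.36 nm peptide-bond length. The wild-type Tar tether of 34 residues
#' gives 12.24 nm.
#'
#' @param n_residues Residue count (> 0, vectorised).
#' @return Contour length in nm.
#' @export
contour_length <- function(n_residues) {
  if (any(n_residues <= 0)) abort("`n_residues` must be positive.")
  n_residues * 0.36
}

#' Tar methylation-site geometry
#'
#' Distances of the four Tar methylation sites from the CheR tethering point
#' (R514), estimated from the axial translation of 0.15 nm per residue along
#' an alpha-helix, in the sequential order of methylation
#' #3 -> #2 -> #1 -> #4. So `m = 1` corresponds to the most distant site #3
#' at 6.75 nm and `m = 4` to site #4 at 3.45 nm; the mean distance is
#' 5.14 nm.
#'
#' @return A tibble with columns `methylation_order` (1--4), `site_label`
#'   and `R_nm`.
#' @examples
#' mean(tar_site_distances()$R_nm)  # 5.14 nm
#' @export
tar_site_distances <- function() {
  tibble(
    methylation_order = 1:4,
    site_label = c("#3", "#2", "#1", "#4"),
    R_nm = c(6.75, 5.70, 4.65, 3.45)
  )
}

#' Tsr methylation-site geometry
#'
#' Distances of the five Tsr methylation sites from the tethering point
#' (R516), in site order #1--#5; mean distance 4.71 nm. Tsr carries five
#' modifiable sites and a shorter (30-residue) tether than Tar.
#'
#' @return A tibble with columns `site_label` and `R_nm`.
#' @export
tsr_site_distances <- function() {
  tibble(
    site_label = paste0("#", 1:5),
    R_nm = c(4.95, 6.00, 7.05, 3.45, 2.10)
  )
}

#' Fit the linear site-distance relation R(m)
#'
#' Ordinary least squares of tether-point distance against methylation
#' level, `R = k * m + R0`. For the Tar geometry this gives a slope of about
#' -1.10 nm per methylation level and an intercept of about 7.86 nm: each
#' successive methylation event happens closer to the tethering point.
#'
#' @param data Data frame with columns `m` (methylation level at which the
#'   site is methylated) and `R_nm`; at least two distinct `m` values. The
#'   default is the Tar geometry.
#' @return An object of class `geometry_fit` with elements `k`, `R0`, `se`
#'   (named), `fit` (the `lm`), `data`. Methods: [tidy()], [glance()].
#' @examples
#' fit_site_distance()
#' @export
fit_site_distance <- function(data = NULL) {
  if (is.null(data)) {
    data <- tar_site_distances() |>
      dplyr::rename(m = "methylation_order")
  }
  data <- as_tibble(data)
  if (!all(c("m", "R_nm") %in% names(data))) {
    abort("`data` must have columns `m` and `R_nm`.")
  }
  if (length(unique(data$m)) < 2) {
    abort("At least two distinct `m` values are required.")
  }
  fit <- lm(R_nm ~ m, data = data)
  s <- suppressWarnings(summary(fit))$coefficients  # exact fits are fine
  structure(
    list(k = unname(coef(fit)["m"]), R0 = unname(coef(fit)["(Intercept)"]),
         se = c(k = s["m", "Std. Error"], R0 = s["(Intercept)", "Std. Error"]),
         fit = fit, data = data),
    class = "geometry_fit"
  )
}

#' @export
print.geometry_fit <- function(x, ...) {
  cat(sprintf("<geometry_fit> R(m) = %.3f * m + %.3f  (se %.3f, %.3f) nm\n",
              x$k, x$R0, x$se["k"], x$se["R0"]))
  invisible(x)
}

#' @export
tidy.geometry_fit <- function(x, ...) {
  tibble(term = c("k", "R0"), estimate = c(x$k, x$R0),
         std.error = unname(x$se[c("k", "R0")]))
}

#' @export
glance.geometry_fit <- function(x, ...) {
  tibble(r.squared = summary(x$fit)$r.squared, n = nrow(x$data))
}

#' Count tether residues in an amino-acid sequence
#'
#' Counts residues in a C-terminal tether sequence, skipping dashes (used as
#' deletion markers) and whitespace, and excluding the terminal CheR-docking
#' pentapeptide NWETF when present. Calibrated against the published tether
#' constructs: the wild-type Tar chain counts 34 residues.
#'
#' @param sequence Amino-acid string over the 20-letter alphabet; dashes and
#'   whitespace allowed and ignored.
#' @return Integer residue count (pentapeptide excluded).
#' @examples
#' count_tether_residues(tar_tether_constructs()$sequence[1])  # 34
#' @export
count_tether_residues <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence)) {
    abort("`sequence` must be a single non-empty string.")
  }
  s <- gsub("[-[:space:]]", "", sequence)
  if (!nzchar(s)) abort("`sequence` contains no residues.")
  s <- toupper(s)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", s)) {
    abort("`sequence` contains characters outside the amino-acid alphabet.")
  }
  if (endsWith(s, "NWETF")) s <- substr(s, 1, nchar(s) - 5)
  nchar(s)
}

#' Published tether constructs
#'
#' The C-terminal tether sequences (including the docking pentapeptide
#' NWETF) of wild-type Tar, three tether-length mutants, and wild-type Tsr,
#' with the tether residue count and contour length.
#'
#' @return A tibble with columns `name`, `description`, `sequence`,
#'   `n_residues`, `L_total_nm`.
#' @export
tar_tether_constructs <- function() {
  seqs <- c(
    pLC113 = "LAASPLTNKPQTPSRPASEQPPAQPRLRIAEQDPNWETF",
    pCZ1   = "LAASPLTNKPQTPSRPASEQPPAQPRLRI---------NWETF",
    pCZ2   = "LAASPLTNKPQTPSRPASEQPP----------------------NWETF",
    pCZ4   = "LAASPLTNKPQTPSRPASEQPPAQPRLRIAEQDPAPRKMAVADSEENWETF",
    Tsr    = "IQQQQRETSAVVKTVTPAAPRKMAVADSEENWETF"
  )
  n <- vapply(seqs, count_tether_residues, integer(1))
  tibble(
    name = names(seqs),
    description = c("wild-type Tar (34 aa chain)", "mutant Tar (29 aa chain)",
                    "mutant Tar (22 aa chain)", "mutant Tar (46 aa chain)",
                    "wild-type Tsr (30 aa chain)"),
    sequence = unname(seqs),
    n_residues = unname(n),
    L_total_nm = contour_length(unname(n))
  )
}
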