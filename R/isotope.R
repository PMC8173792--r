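#' Isotope reference standards
#'
#' Heavy/light isotope ratios of the international reference standards used
#' in delta notation: Pee Dee Belemnite for carbon (13C/12C) and atmospheric
#' N2 for nitrogen (15N/14N).
#'
#' @param element `"C"` or `"N"`.
#' @return A list with components `element` and `reference_ratio`.
#' @examples
#' iso_standard("C")$reference_ratio  # 0.0112372
#' @export
iso_standard <- function(element = c("C", "N")) {
  element <- match.arg(element)
  ratio <- switch(element, C = 0.0112372, N = 0.0036765)
  structure(list(element = element, reference_ratio = ratio),
            class = "iso_standard")
}

#' Convert delta notation to atom percent
#'
#' Atom percent (AP) is the percentage of an element's atoms that are the
#' heavy isotope, `AP = 100 R / (1 + R)` where the sample ratio
#' `R = R_std (1 + delta/1000)`.
#'
#' @param delta Per-mil deviation(s) from the reference standard. Must be
#'   finite and greater than -1000 (R > 0).
#' @param standard An [iso_standard()] or an element code `"C"`/`"N"`.
#' @return Atom percent, in (0, 100).
#' @examples
#' delta_to_atom_percent(0, "C")  # 1.11123 (natural PDB abundance)
#' @export
delta_to_atom_percent <- function(delta, standard = "C") {
  standard <- as_iso_standard(standard)
  if (!all(is.finite(delta))) {
    stop("`delta` must be finite", call. = FALSE)
  }
  if (any(delta <= -1000)) {
    stop("`delta` must exceed -1000 per mil (isotope ratio must stay positive)",
         call. = FALSE)
  }
  r <- standard$reference_ratio * (1 + delta / 1000)
  100 * r / (1 + r)
}

#' Convert atom percent to delta notation
#'
#' Exact inverse of [delta_to_atom_percent()].
#'
#' @param atom_percent Atom percent value(s), strictly inside (0, 100).
#' @inheritParams delta_to_atom_percent
#' @return Delta values in per mil.
#' @export
atom_percent_to_delta <- function(atom_percent, standard = "C") {
  standard <- as_iso_standard(standard)
  if (!all(is.finite(atom_percent)) ||
      any(atom_percent <= 0) || any(atom_percent >= 100)) {
    stop("`atom_percent` must lie strictly between 0 and 100", call. = FALSE)
  }
  r <- atom_percent / (100 - atom_percent)
  (r / standard$reference_ratio - 1) * 1000
}

as_iso_standard <- function(x) {
  if (inherits(x, "iso_standard")) return(x)
  iso_standard(x)
}

#' Atom percent excess
#'
#' Enrichment above a measured natural-abundance control,
#' `APE = AP_sample - AP_control`. Negative values (control above sample)
#' are retained and flagged via the `"negative"` attribute rather than
#' truncated, so downstream tests keep their distributional validity.
#'
#' @param ap_sample,ap_control Atom percent values in (0, 100).
#' @return APE in percentage points, with attribute `negative` (logical).
#' @examples
#' atom_percent_excess(2.27, 1.081)  # 1.189
#' @export
atom_percent_excess <- function(ap_sample, ap_control) {
  stopifnot(all(ap_sample > 0 & ap_sample < 100),
            all(ap_control > 0 & ap_control < 100))
  ape <- ap_sample - ap_control
  attr(ape, "negative") <- ape < 0
  ape
}

#' Relative enrichment of the algal fraction
#'
#' Expresses symbiont enrichment as a percentage of host enrichment,
#' `(APE_algal / APE_host) * 100`.
#'
#' @param ape_algal,ape_host Atom percent excess values; `ape_host` must be
#'   non-zero.
#' @return Percent of host enrichment.
#' @export
relative_enrichment <- function(ape_algal, ape_host) {
  if (any(ape_host == 0)) {
    stop("`ape_host` is zero: relative enrichment undefined", call. = FALSE)
  }
  as.numeric(ape_algal) / as.numeric(ape_host) * 100
}

#' Invert a spike mass balance
#'
#' Samples too small (or too enriched) for direct isotope-ratio measurement
#' are mixed with a certified standard (e.g. acetanilide); the sample's own
#' atom percent is then recovered from the mass balance
#' `AP_mix (m_s f_s + m_std f_std) = AP_s m_s f_s + AP_std m_std f_std`,
#' where `m` are masses and `f` the element mass fractions.
#'
#' @param measured_AP_mix Atom percent measured on the mixture.
#' @param sample_mass,standard_mass Masses (mg) of sample and spiked
#'   standard; `standard_mass = 0` returns the measurement unchanged.
#' @param standard_AP Atom percent of the standard (natural abundance for an
#'   unenriched spike).
#' @param element_mass_fraction_sample,element_mass_fraction_standard Mass
#'   fraction of the element of interest in sample and standard, in (0, 1].
#'   For acetanilide (C8H9NO) see [acetanilide_fraction()].
#' @return The sample's atom percent.
#' @export
invert_spike <- function(measured_AP_mix, sample_mass, standard_mass,
                         standard_AP,
                         element_mass_fraction_sample,
                         element_mass_fraction_standard) {
  stopifnot(sample_mass >= 0, standard_mass >= 0,
            element_mass_fraction_sample > 0,
            element_mass_fraction_sample <= 1,
            element_mass_fraction_standard > 0,
            element_mass_fraction_standard <= 1)
  if (standard_mass == 0) return(measured_AP_mix)
  es <- sample_mass * element_mass_fraction_sample
  estd <- standard_mass * element_mass_fraction_standard
  if (es == 0) {
    stop("degenerate mixture: sample contributes no element mass",
         call. = FALSE)
  }
  (measured_AP_mix * (es + estd) - standard_AP * estd) / es
}

#' Element mass fractions of acetanilide
#'
#' Computed from the molecular formula C8H9NO with IUPAC atomic weights
#' (C 12.011, H 1.008, N 14.007, O 15.999).
#'
#' @param element `"C"` or `"N"`.
#' @return Mass fraction of the element in acetanilide.
#' @export
acetanilide_fraction <- function(element = c("C", "N")) {
  element <- match.arg(element)
  m <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999)
  total <- 8 * m["C"] + 9 * m["H"] + m["N"] + m["O"]
  unname(switch(element, C = 8 * m["C"], N = m["N"]) / total)
}

#' Machine precision as percent relative standard deviation
#'
#' `%RSD = 100 sd / mean` over replicate readings of a certified standard,
#' using the sample (n - 1) standard deviation.
#'
#' @param readings Numeric vector of at least two replicate readings with a
#'   non-zero mean.
#' @return Percent relative standard deviation.
#' @examples
#' machine_precision(c(9, 11))  # 14.14
#' @export
machine_precision <- function(readings) {
  if (length(readings) < 2) {
    stop("need at least two readings", call. = FALSE)
  }
  m <- mean(readings)
  if (m == 0) stop("mean of readings is zero: %RSD undefined", call. = FALSE)
  100 * stats::sd(readings) / m
}

#' Average duplicate isotope readings
#'
#' Instrument runs measure each sample fraction in duplicate; the mean of
#' the two readings is used downstream. Single readings (e.g. low-mass algal
#' pellets) pass through unchanged. More than two replicates per key is
#' unexpected and triggers a warning, but the mean is still taken.
#'
#' @param measurements A data frame with columns `sample_id`, `fraction`,
#'   `element`, `value`, and optionally any metadata columns (constant
#'   within a key, e.g. `treatment`, `timepoint`, `value_type`).
#' @return One row per (sample_id, fraction, element) with `value` the
#'   replicate mean and `n_replicates` recording how many readings entered.
#' @export
average_duplicates <- function(measurements) {
  req <- c("sample_id", "fraction", "element", "value")
  miss <- setdiff(req, names(measurements))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(measurements) == 0) {
    stop("no measurements supplied", call. = FALSE)
  }
  key <- interaction(measurements$sample_id, measurements$fraction,
                     measurements$element, drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(measurements)), key)
  sizes <- lengths(idx)
  if (any(sizes > 2)) {
    warning(sum(sizes > 2), " group(s) with more than two replicates; ",
            "mean taken over all readings")
  }
  out <- do.call(rbind, lapply(idx, function(i) {
    row <- measurements[i[1], , drop = FALSE]
    row$value <- mean(measurements$value[i])
    row$n_replicates <- length(i)
    row
  }))
  rownames(out) <- NULL
  drop_col <- intersect("replicate_index", names(out))
  out[, setdiff(names(out), drop_col), drop = FALSE]
}

#' Atom percent excess table against measured controls
#'
#' Takes a tidy table of averaged atom-percent measurements, extracts the
#' natural-abundance controls (timepoint `"T0"`), and returns APE for every
#' non-control row. Controls can be pooled across treatments (default) or
#' matched within symbiotic state.
#'
#' @param ap_table Data frame with columns `sample_id`, `treatment`,
#'   `fraction`, `timepoint`, `element`, `value` (atom percent).
#' @param control_mode `"pooled"` (one mean control AP per element-fraction)
#'   or `"per_state"` (controls matched on symbiotic state, i.e. treatments
#'   beginning "Apo" vs "Sym").
#' @return The non-control rows with added columns `ap_control` and `ape`.
#' @export
ape_table <- function(ap_table, control_mode = c("pooled", "per_state")) {
  control_mode <- match.arg(control_mode)
  is_ctrl <- ap_table$timepoint == "T0"
  if (!any(is_ctrl)) stop("no T0 control rows found", call. = FALSE)
  ctl <- ap_table[is_ctrl, , drop = FALSE]
  smp <- ap_table[!is_ctrl, , drop = FALSE]
  state <- function(tr) ifelse(grepl("^Apo", tr), "apo", "sym")
  ckey <- paste(ctl$element, ctl$fraction,
                if (control_mode == "per_state") state(ctl$treatment) else "")
  cmean <- tapply(ctl$value, ckey, mean)
  skey <- paste(smp$element, smp$fraction,
                if (control_mode == "per_state") state(smp$treatment) else "")
  smp$ap_control <- as.numeric(cmean[skey])
  if (anyNA(smp$ap_control)) {
    stop("no matching T0 control for some element/fraction groups",
         call. = FALSE)
  }
  smp$ape <- as.numeric(atom_percent_excess(smp$value, smp$ap_control))
  smp
}
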