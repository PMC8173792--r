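#' Default configuration for the synthetic study generator
#'
#' Bundles every tunable of the synthetic holobiont experiment: the
#' pulse-chase design (3 treatments x 5 medusae x 4 timepoints, host and
#' algal fractions, C and N), instrument noise as percent relative
#' standard deviation, respirometry ground truth, the published
#' calibration polynomials for the wet-weight ~ bell-diameter generator,
#' and the bacterial community truth (dominance, dispersion, planted core
#' and contaminant sets).
#'
#' @param seed Integer seed; all generators are fully deterministic given
#'   it.
#' @param n_per_treatment Medusae per treatment.
#' @param rsd_c,rsd_n Measurement precision (%RSD) applied as relative
#'   Gaussian noise on the atom-percent scale for C and N.
#' @param do_noise_sd Dissolved-oxygen reading noise, mg L^-1.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_per_treatment = 5, rsd_c = 1.4,
                       rsd_n = 4.1, do_noise_sd = 0.05) {
  traj <- list(
    # mean atom percent per treatment/fraction: T0, pulse, chase3h, chase6h
    C = list(
      SymL = list(host  = c(1.081, 1.50, 2.20, 1.90),
                  algal = c(1.081, 2.60, 3.30, 2.90)),
      SymD = list(host  = c(1.081, 1.13, 1.11, 1.10),
                  algal = c(1.081, 1.11, 1.12, 1.13)),
      ApoL = list(host  = c(1.081, 1.12, 1.11, 1.10),
                  algal = c(1.081, 1.11, 1.10, 1.10))),
    N = list(
      SymL = list(host  = c(0.368, 0.78, 0.50, 0.45),
                  algal = c(0.368, 0.45, 0.50, 0.55)),
      SymD = list(host  = c(0.368, 0.76, 0.48, 0.44),
                  algal = c(0.368, 0.42, 0.46, 0.50)),
      ApoL = list(host  = c(0.368, 0.80, 0.40, 0.385),
                  algal = c(0.368, 0.42, 0.40, 0.39))))
  structure(list(
    seed = seed,
    n_per_treatment = n_per_treatment,
    treatments = c("SymL", "SymD", "ApoL"),
    timepoints = c("T0", "pulse", "chase3h", "chase6h"),
    trajectories = traj,
    natural_ap = c(C = 1.081, N = 0.368),
    rsd = c(C = rsd_c, N = rsd_n),
    # heterotrophic feeding: per-medusa host APE range and the relative
    # enrichment of the algal fraction (mean, sd), per element
    fed = list(n = 4,
               host_ape_range = list(C = c(1.25, 1.80), N = c(0.50, 0.75)),
               rel_enrichment = list(C = c(mean = 36.7, sd = 4.6),
                                     N = c(mean = 70.3, sd = 4.0))),
    respirometry = list(
      SymL = list(kind = "Pn", light = TRUE, mean = 0.028, sd = 0.010),
      SymD = list(kind = "R", light = FALSE, mean = 0.028, sd = 0.014),
      ApoL = list(kind = "R", light = TRUE, mean = 0.049, sd = 0.008)),
    do_noise_sd = do_noise_sd,
    do_start = 6.8,
    chamber_volume_l = 1.0,
    duration_h = 5,
    allometry = list(
      symbiotic = list(coef = c(8.540, -0.494, 0.009), n = 35,
                       bd_range = c(30, 80), sigma = 0.05),
      aposymbiotic = list(coef = c(-1.440, 0.100), n = 12,
                          bd_range = c(20, 40), sigma = 0.05)),
    community = list(
      depth_range = c(12000, 20000),
      control_spill_reads = 600,
      concentration = c(SymL = 150, SymD = 300, ApoL = 20),
      dominance_concentration = c(SymL = 400, SymD = 1200, ApoL = 250),
      n_tail = 100,
      tail_mass_sym = 0.020,
      tail_mass_apo = 0.045,
      # bleached hosts are open to invasion: each aposymbiotic sample hosts
      # its own random subset of otherwise-rare taxa, raising both richness
      # and between-sample turnover
      invaders = list(SymL = c(0, 0), SymD = c(0, 0), ApoL = c(20, 70),
                      outlier = c(85, 95), mass = 0.35),
      dominance = 0.85,          # two-ASV share of reads, typical sample
      dominance_outlier = 0.66,  # eroded dominance in the ApoL outlier
      dominant_split = 0.65 / 0.85,  # Moraxellaceae share of the dominants
      outlier_sample = "ApoLPul3")
  ), class = "sim_config")
}

sim_seed <- function(config, offset) {
  (config$seed * 97 + offset) %% .Machine$integer.max
}

#' Simulate the pulse-chase stable-isotope experiment
#'
#' Emits duplicated atom-percent readings for every treatment x medusa x
#' timepoint x fraction x element cell, with Gaussian noise at the
#' configured %RSD around the treatment-mean trajectories, plus four fed
#' medusae from the heterotrophic feeding experiment. Three designated
#' low-mass algal cells yield a single reading (mirroring real instrument
#' runs). Ground truth (trajectory means, fed relative-enrichment draws)
#' is returned alongside.
#'
#' @param config A [sim_config()].
#' @return List with `measurements` (tidy table in the
#'   [read_isotope_table()] dialect) and `truth`.
#' @export
simulate_sia <- function(config = sim_config()) {
  withr_seed(sim_seed(config, 1), {
    rows <- list()
    single_cells <- c("SymD.pulse.1.algal", "SymD.chase6h.1.algal",
                      "SymL.chase6h.1.algal")
    for (el in c("C", "N")) {
      rsd <- config$rsd[[el]]
      for (tr in config$treatments) {
        for (ti in seq_along(config$timepoints)) {
          tp <- config$timepoints[ti]
          for (fr in c("host", "algal")) {
            mu <- config$trajectories[[el]][[tr]][[fr]][ti]
            for (i in seq_len(config$n_per_treatment)) {
              n_rep <- if (paste(tr, tp, i, fr, sep = ".") %in%
                             single_cells) 1L else 2L
              vals <- mu * (1 + stats::rnorm(n_rep, 0, rsd / 100))
              rows[[length(rows) + 1L]] <- data.frame(
                sample_id = paste0(tr, tp, i), treatment = tr,
                fraction = fr, timepoint = tp, element = el,
                value = vals, value_type = "atom_percent",
                replicate_index = seq_len(n_rep))
            }
          }
        }
      }
    }
    # heterotrophic feeding experiment
    fed_truth <- list()
    for (el in c("C", "N")) {
      rng <- config$fed$host_ape_range[[el]]
      rel <- config$fed$rel_enrichment[[el]]
      host_ape <- stats::runif(config$fed$n, rng[1], rng[2])
      rel_draw <- stats::rnorm(config$fed$n, rel[["mean"]], rel[["sd"]])
      fed_truth[[el]] <- data.frame(sample_id = paste0("Fed", seq_len(config$fed$n)),
                                    host_ape = host_ape,
                                    relative_enrichment = rel_draw)
      for (i in seq_len(config$fed$n)) {
        for (fr in c("host", "algal")) {
          mu <- config$natural_ap[[el]] +
            if (fr == "host") host_ape[i] else host_ape[i] * rel_draw[i] / 100
          vals <- mu * (1 + stats::rnorm(2, 0, config$rsd[[el]] / 100))
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = paste0("Fed", i), treatment = "fed",
            fraction = fr, timepoint = "pulse", element = el,
            value = vals, value_type = "atom_percent",
            replicate_index = 1:2)
        }
      }
    }
    measurements <- do.call(rbind, rows)
    rownames(measurements) <- NULL
    list(measurements = measurements,
         truth = list(trajectories = config$trajectories, fed = fed_truth))
  })
}

#' Simulate closed-chamber respirometry incubations
#'
#' Draws a true mass-specific rate per animal from the configured
#' treatment distributions, inverts the oxygen-flux equation to produce
#' end-of-incubation dissolved-oxygen readings, and adds reading noise to
#' both DO measurements. With `config$do_noise_sd = 0` the rates are
#' recovered exactly by [oxygen_flux()].
#'
#' @param config A [sim_config()].
#' @return List with `records` (the [read_incubation_table()] dialect) and
#'   `truth` (per-record true signed rate and kind).
#' @export
simulate_respirometry <- function(config = sim_config()) {
  withr_seed(sim_seed(config, 2), {
    rows <- list()
    truth <- list()
    for (tr in config$treatments) {
      spec <- config$respirometry[[tr]]
      for (i in seq_len(config$n_per_treatment)) {
        ww <- stats::runif(1, 2, 6)
        magnitude <- abs(stats::rnorm(1, spec$mean, spec$sd))
        signed <- if (spec$kind == "R") -magnitude else magnitude
        v_med <- medusa_volume(ww)
        d_o2 <- signed * config$duration_h * ww /
          (config$chamber_volume_l - v_med)
        id <- paste0(tr, "Resp", i)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = id, treatment = tr,
          do_start = config$do_start + stats::rnorm(1, 0, config$do_noise_sd),
          do_end = config$do_start + d_o2 +
            stats::rnorm(1, 0, config$do_noise_sd),
          chamber_volume_l = config$chamber_volume_l,
          wet_weight_g = ww, duration_h = config$duration_h,
          light = spec$light)
        truth[[length(truth) + 1L]] <- data.frame(
          sample_id = id, treatment = tr, kind = spec$kind,
          true_rate = signed)
      }
    }
    list(records = do.call(rbind, rows), truth = do.call(rbind, truth))
  })
}

#' Simulate wet-weight / bell-diameter calibration pairs
#'
#' Draws bell diameters uniformly over the calibration range and evaluates
#' the configured generating polynomial (second degree for symbiotic,
#' first degree for aposymbiotic animals) plus Gaussian noise.
#'
#' @param config A [sim_config()].
#' @return List with `pairs` (`state`, `bd_mm`, `ww_g`) and `truth` (the
#'   generating coefficients and noise sd per state).
#' @export
simulate_allometry <- function(config = sim_config()) {
  withr_seed(sim_seed(config, 3), {
    rows <- lapply(names(config$allometry), function(st) {
      a <- config$allometry[[st]]
      bd <- stats::runif(a$n, a$bd_range[1], a$bd_range[2])
      mu <- vapply(bd, function(x) sum(a$coef * x^(seq_along(a$coef) - 1)),
                   numeric(1))
      data.frame(state = st, bd_mm = bd,
                 ww_g = mu + stats::rnorm(a$n, 0, a$sigma))
    })
    list(pairs = do.call(rbind, rows), truth = config$allometry)
  })
}

# taxonomy helper: build a SILVA-style lineage string
lineage <- function(class, order, family, genus) {
  paste0("d__Bacteria;p__Proteobacteria;c__", class, ";o__", order,
         ";f__", family, ";g__", genus)
}

community_pool <- function(config) {
  com <- config$community
  asv <- function(id, tax, role) data.frame(asv_id = id, taxonomy = tax,
                                            role = role)
  structured <- rbind(
    asv("ASV_0001", lineage("Gammaproteobacteria", "Pseudomonadales",
                            "Moraxellaceae", "Acinetobacter"), "dominant"),
    asv("ASV_0002", lineage("Gammaproteobacteria", "Pseudomonadales",
                            "Pseudomonadaceae", "Pseudomonas"), "dominant"),
    asv("ASV_0003", lineage("Gammaproteobacteria", "Burkholderiales",
                            "Oxalobacteraceae", "Massilia"), "core"),
    asv("ASV_0004", lineage("Alphaproteobacteria", "Sphingomonadales",
                            "Sphingomonadaceae", "Sphingobium"), "core"),
    asv("ASV_0005", lineage("Alphaproteobacteria", "Rhodobacterales",
                            "Rhodobacteraceae", "Paracoccus"), "core"),
    asv("ASV_0006", lineage("Bacteroidia", "Flavobacteriales",
                            "Flavobacteriaceae", "Flavobacterium"), "core"),
    asv("ASV_0007", lineage("Gammaproteobacteria", "Burkholderiales",
                            "Comamonadaceae", "Comamonas"), "core"),
    asv("ASV_0008", lineage("Gammaproteobacteria", "Pseudomonadales",
                            "Moraxellaceae", "Acinetobacter"), "core"),
    asv("ASV_0009", lineage("Gammaproteobacteria", "Vibrionales",
                            "Vibrionaceae", "Vibrio"), "core"),
    asv("ASV_0010", lineage("Gammaproteobacteria", "Enterobacterales",
                            "Erwiniaceae", "Pantoea"), "core"),
    asv("ASV_0011", lineage("Gammaproteobacteria", "Pseudomonadales",
                            "Moraxellaceae", "Acinetobacter"), "symbiome"),
    asv("ASV_0012", lineage("Alphaproteobacteria", "Rhodobacterales",
                            "Rhodobacteraceae", "Ruegeria"), "symbiome"),
    asv("ASV_0013", lineage("Gammaproteobacteria", "Cellvibrionales",
                            "Cellvibrionaceae", "Cellvibrio"), "apobiome"),
    asv("ASV_0014", lineage("Gammaproteobacteria", "Burkholderiales",
                            "Burkholderiaceae", "Ralstonia"), "apobiome"))
  tail_families <- c("Rhizobiaceae", "Alteromonadaceae", "Halomonadaceae",
                     "Saprospiraceae", "Hyphomonadaceae", "Kiloniellaceae",
                     "Cryomorphaceae", "Marinobacteraceae",
                     "Moraxellaceae", "Spirosomaceae")
  n_tail <- com$n_tail
  tail_ids <- sprintf("ASV_%04d", 14 + seq_len(n_tail))
  tails <- data.frame(
    asv_id = tail_ids,
    taxonomy = lineage("Gammaproteobacteria", "various",
                       rep_len(tail_families, n_tail),
                       "uncultured"),
    role = "tail")
  contams <- data.frame(
    asv_id = sprintf("ASV_%04d", 14 + n_tail + 1:7),
    taxonomy = c(
      lineage("Bacilli", "Staphylococcales", "Staphylococcaceae",
              "Staphylococcus"),
      lineage("Actinobacteria", "Propionibacteriales",
              "Propionibacteriaceae", "Cutibacterium"),
      lineage("Gammaproteobacteria", "Burkholderiales", "Burkholderiaceae",
              "Burkholderia"),
      lineage("Bacilli", "Lactobacillales", "Streptococcaceae",
              "Streptococcus"),
      lineage("Actinobacteria", "Corynebacteriales", "Corynebacteriaceae",
              "Corynebacterium"),
      lineage("Alphaproteobacteria", "Sphingomonadales", "Sphingomonadaceae",
              "Sphingomonas"),
      lineage("Gammaproteobacteria", "Enterobacterales", "Enterobacteriaceae",
              "Escherichia-Shigella")),
    role = c(rep("contaminant_control_only", 6), "contaminant_shared"))
  rbind(structured, tails, contams)
}

# sub-dominant base relative abundances (summing to 1 over the non-dominant
# biological pool) for one sample
community_rest_base <- function(pool, config, group, outlier = FALSE) {
  com <- config$community
  rest_ids <- pool$asv_id[!pool$role %in%
                            c("dominant", "contaminant_control_only",
                              "contaminant_shared")]
  p <- stats::setNames(numeric(length(rest_ids)), rest_ids)
  tail_ids <- pool$asv_id[pool$role == "tail"]
  n_tail <- length(tail_ids)
  # geometric decay over the tail so a handful of tail taxa are common and
  # the rest sporadic
  tail_shape <- 0.94^(seq_len(n_tail) - 1)
  tail_shape <- tail_shape / sum(tail_shape)
  tail_mass <- if (group == "ApoL") com$tail_mass_apo else com$tail_mass_sym
  p[tail_ids] <- tail_mass * tail_shape
  mid_core <- pool$asv_id[pool$role == "core"]
  p[mid_core] <- seq(0.025, 0.006, length.out = length(mid_core))
  p["ASV_0011"] <- if (group == "ApoL") 0.0010 else 0.0045
  p["ASV_0012"] <- if (group == "ApoL") 0.0010 else 0.0040
  p["ASV_0013"] <- if (group == "ApoL") 0.0045 else 0.0010
  p["ASV_0014"] <- if (group == "ApoL") 0.0040 else 0.0010
  if (outlier) {
    # the outlier's eroded dominance is partly taken up by a Moraxellaceae
    # tail taxon, so family-level dominance is retained
    p[tail_ids[9]] <- p[tail_ids[9]] + 0.35
  }
  p / sum(p)
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  stats::setNames(x / sum(x), names(alpha))
}

rbeta_mean <- function(mean, conc) {
  stats::rbeta(1, mean * conc, (1 - mean) * conc)
}

#' Simulate a 16S ASV table with planted structure
#'
#' Generates a 16-library experiment (5 SymL, 5 SymD, 5 ApoL medusae plus
#' one extraction control) from a Dirichlet-multinomial model: two
#' dominant taxa carry ~85% of reads, the aposymbiotic group has a 10-fold
#' lower Dirichlet concentration (hence higher Bray-Curtis dispersion) and
#' one high-richness outlier sample, and membership structure is planted
#' exactly - a 10-ASV core present in all medusae, two extra symbiome and
#' two extra apobiome members, and 7 contaminants (6 exclusive to the
#' control) that meet the 10% control-fraction rule by construction. A
#' random bifurcating tree with exponential branch lengths covers all
#' ASVs.
#'
#' @param config A [sim_config()].
#' @return List with `table` (an [asv_table()] including the control),
#'   `tree` (phylo), and `truth` (planted sets and parameters).
#' @export
simulate_asv_table <- function(config = sim_config()) {
  withr_seed(sim_seed(config, 4), {
    com <- config$community
    pool <- community_pool(config)
    bio <- pool[!grepl("contaminant", pool$role), ]
    treatments <- rep(config$treatments, each = config$n_per_treatment)
    ids <- paste0(treatments, "Pul",
                  rep(seq_len(config$n_per_treatment),
                      times = length(config$treatments)))
    depths <- round(stats::runif(length(ids), com$depth_range[1],
                                 com$depth_range[2]))
    counts <- matrix(0L, nrow = length(ids) + 1, ncol = nrow(pool),
                     dimnames = list(c(ids, "Control1"), pool$asv_id))
    tail_ids <- pool$asv_id[pool$role == "tail"]
    for (s in seq_along(ids)) {
      tr <- treatments[s]
      outlier <- ids[s] == com$outlier_sample
      # dominant share: a Beta draw whose concentration mirrors the
      # treatment ordering of within-group variability
      dconc <- com$dominance_concentration[[tr]]
      s_dom <- rbeta_mean(if (outlier) com$dominance_outlier
                          else com$dominance, dconc)
      split <- rbeta_mean(com$dominant_split, dconc)
      rest_base <- community_rest_base(pool, config, tr, outlier)
      alpha0 <- com$concentration[[tr]]
      rest_p <- rdirichlet1(alpha0 * rest_base)
      inv_range <- com$invaders[[if (outlier) "outlier" else tr]]
      if (inv_range[2] > 0) {
        # invaders are drawn per sample with a flat Dirichlet of their own:
        # which taxa invade varies between samples (turnover), but the ones
        # that do are reliably detectable (richness)
        n_inv <- sample(seq(inv_range[1], inv_range[2]), 1)
        inv <- sample(tail_ids, n_inv)
        inv_p <- stats::setNames(rdirichlet1(rep(1, n_inv)), inv)
        w <- com$invaders$mass
        rest_p <- (1 - w) * rest_p
        rest_p[inv] <- rest_p[inv] + w * inv_p
      }
      pvec <- c(stats::setNames(c(s_dom * split, s_dom * (1 - split)),
                                c("ASV_0001", "ASV_0002")),
                (1 - s_dom) * rest_p)
      counts[s, names(pvec)] <- stats::rmultinom(1, depths[s], pvec)[, 1]
    }
    # planted membership: force presence / absence
    core_ids <- pool$asv_id[pool$role %in% c("dominant", "core")]
    sym_rows <- which(treatments %in% c("SymL", "SymD"))
    apo_rows <- which(treatments == "ApoL")
    force_present <- function(rows, id) {
      z <- rows[counts[rows, id] == 0]
      counts[z, id] <<- sample(2:5, length(z), replace = TRUE)
    }
    for (id in core_ids) force_present(seq_along(ids), id)
    for (id in c("ASV_0011", "ASV_0012")) force_present(sym_rows, id)
    for (id in c("ASV_0013", "ASV_0014")) force_present(apo_rows, id)
    # forced absences keep membership sets exact; zeroing the group's
    # minimum-count sample loses (almost) no reads
    force_absent <- function(rows, id) {
      i <- rows[counts[rows, id] == min(counts[rows, id])]
      counts[if (length(i) > 1) sample(i, 1) else i, id] <<- 0L
    }
    force_absent(apo_rows, "ASV_0011")
    force_absent(apo_rows, "ASV_0012")
    force_absent(sym_rows, "ASV_0013")
    force_absent(sym_rows, "ASV_0014")
    for (id in tail_ids) {
      force_absent(sym_rows, id)
      force_absent(apo_rows, id)
    }
    # extraction control: spill-over of the abundant biological taxa plus
    # planted contaminants
    spill_p <- c(com$dominance * com$dominant_split,
                 com$dominance * (1 - com$dominant_split),
                 (1 - com$dominance) *
                   community_rest_base(pool, config, "SymL")[
                     setdiff(core_ids, c("ASV_0001", "ASV_0002"))])
    counts["Control1", core_ids] <-
      stats::rmultinom(1, com$control_spill_reads, spill_p / sum(spill_p))[, 1]
    ctrl_only <- pool$asv_id[pool$role == "contaminant_control_only"]
    counts["Control1", ctrl_only] <- round(stats::runif(6, 50, 400))
    shared <- pool$asv_id[pool$role == "contaminant_shared"]
    counts["Control1", shared] <- 300L
    counts[sample(seq_along(ids), 3), shared] <- c(60L, 50L, 40L)
    meta <- data.frame(sample_id = rownames(counts),
                       treatment = c(treatments, "control"),
                       is_control = c(rep(FALSE, length(ids)), TRUE))
    tab <- asv_table(counts, stats::setNames(pool$taxonomy, pool$asv_id),
                     meta)
    tree <- ape::rtree(nrow(pool), rooted = TRUE, br = stats::rexp,
                       rate = 500)
    tree$tip.label <- sample(pool$asv_id)
    list(table = tab, tree = tree,
         truth = list(
           contaminants = pool$asv_id[grepl("contaminant", pool$role)],
           control_only = ctrl_only,
           core = core_ids,
           symbiome = c(core_ids, "ASV_0011", "ASV_0012"),
           apobiome = c(core_ids, "ASV_0013", "ASV_0014"),
           dominant = c("ASV_0001", "ASV_0002"),
           concentration = com$concentration))
  })
}

#' Simulate an enrichment ~ covariate regression dataset
#'
#' Draws the covariate uniformly over `x_range`, evaluates the generating
#' line, and adds Gaussian noise with the sd that makes the expected
#' R-squared equal `r2_target` (noise variance = signal variance x
#' (1 - r2) / r2 under uniform-x sampling).
#'
#' @param intercept,slope Generating line.
#' @param n Number of observations.
#' @param x_range Covariate range.
#' @param r2_target Target coefficient of determination in (0, 1).
#' @param seed Integer seed.
#' @return List with `data` (x, y), `truth` (coefficients and noise sd).
#' @export
simulate_enrichment_regression <- function(intercept, slope, n, x_range,
                                           r2_target, seed = 1) {
  stopifnot(r2_target > 0, r2_target < 1, n >= 3)
  var_signal <- slope^2 * diff(x_range)^2 / 12
  sigma <- sqrt(var_signal * (1 - r2_target) / r2_target)
  withr_seed(seed, {
    x <- stats::runif(n, x_range[1], x_range[2])
    y <- intercept + slope * x + stats::rnorm(n, 0, sigma)
    list(data = data.frame(x = x, y = y),
         truth = list(intercept = intercept, slope = slope, sigma = sigma))
  })
}
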