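#' Configuration for the synthetic study panel
#'
#' Defaults emulate a 17-cell-line sarcoma-like panel at desk scale: 2000
#' proteins (60 of them kinases), 4000 p-sites, 30 drugs screened over a
#' 10-point 1:3 dilution ladder topping out at 10 mM-scale stock (in
#' micromolar), log-normal intensities with row-wise missingness, and planted
#' causal structure: per-line elevated kinase activity that lowers the ED50
#' of drugs targeting those kinases, periodic-protein phase signatures, and
#' linear abundance-response marker relationships.
#'
#' The planted activity effect drives both the molecular layers and the drug
#' phenotype: the ED50 sensitisation of a matched drug scales as
#' `ed50_sensitization^(active_effect_log10 / 0.7)`, so a zero molecular
#' effect implies no phenotypic effect (the causal chain is broken, not just
#' attenuated).
#'
#' @param n_cell_lines,n_proteins,n_psites,n_kinases,n_drugs panel sizes.
#' @param doses dose ladder in micromolar.
#' @param missing_rate fraction of cells set missing, uniformly at random.
#' @param noise_sd_log10 SD of per-cell log10 intensity noise.
#' @param seed integer master seed; child seeds fan out per table so
#'   regenerating one table does not perturb the others.
#' @param active_effect_log10 planted log10 abundance/phosphorylation shift
#'   for active (cell line, kinase) pairs (default +0.7).
#' @param n_active_pairs number of planted active (line, kinase) pairs.
#' @param ed50_sensitization fold by which a matched drug's ED50 drops in a
#'   line with an active target kinase (default 100).
#' @param n_marker_links number of planted linear feature-AUC links.
#' @param n_substrates_per_kinase annotated substrate sites per kinase.
#' @param signal_noise_frac screen signal noise SD as a fraction of the
#'   negative-control mean (default 0.02, the order of the screen's reported
#'   reproducibility).
#' @param n_periodic_proteins periodic proteins split over 5 clusters
#'   (default 119).
#' @param periodic_effect_log10 log10 boost of a line's dominant cluster.
#' @return a `panel_config` list.
#' @export
panel_config <- function(n_cell_lines = 17, n_proteins = 2000,
                         n_psites = 4000, n_kinases = 60, n_drugs = 30,
                         doses = 10000 / 3^(9:0),
                         missing_rate = 0.1, noise_sd_log10 = 0.2,
                         seed = 1,
                         active_effect_log10 = 0.7, n_active_pairs = 5,
                         ed50_sensitization = 100,
                         n_marker_links = 5,
                         n_substrates_per_kinase = 5,
                         signal_noise_frac = 0.02,
                         n_periodic_proteins = 119,
                         periodic_effect_log10 = 0.7) {
  stopifnot(n_cell_lines >= 1, n_proteins >= 1, n_psites >= 1,
            n_kinases >= 1, n_drugs >= 1,
            missing_rate >= 0, missing_rate < 1,
            all(doses > 0),
            n_periodic_proteins >= 5,
            n_periodic_proteins + n_marker_links <= n_proteins - n_kinases,
            n_active_pairs <= min(n_cell_lines, n_kinases),
            n_psites >= 3 * n_kinases + n_substrates_per_kinase)
  structure(as.list(environment()), class = "panel_config")
}

child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000003 + k) %% 2147483647)
}

#' Generate the full synthetic study panel
#'
#' @param config a [panel_config()].
#' @return list with `proteome` and `phospho` (linear-scale
#'   `abundance_matrix` objects), `annotations` (`annotation_set`), `screen`
#'   (long-format well data.frame) and `truth` (planted-truth record: active
#'   pairs, drug targets, true curve parameters, true AUC matrix, marker
#'   links, periodic profile, the designated cell-cycle-linked drug).
#' @export
generate_panel <- function(config = panel_config()) {
  stopifnot(inherits(config, "panel_config"))
  lines <- sprintf("CL%02d", seq_len(config$n_cell_lines))
  kinases <- sprintf("KIN%02d", seq_len(config$n_kinases))
  others <- sprintf("PROT%04d",
                    seq_len(config$n_proteins - config$n_kinases))
  proteins <- c(kinases, others)

  ## --- site layout (which site sits on which protein) ----------------------
  layout <- with_seed(child_seed(config$seed, 1L), {
    # each kinase gets one activation-loop site and two further own sites;
    # the remaining sites land on random proteins
    n_fixed <- 3L * config$n_kinases
    if (config$n_psites < n_fixed)
      stop("n_psites too small for the kinase site layout")
    host <- c(rep(kinases, each = 3L),
              sample(proteins, config$n_psites - n_fixed, replace = TRUE))
    residue <- sample(c("S", "T", "Y"), config$n_psites, replace = TRUE,
                      prob = c(0.75, 0.2, 0.05))
    pos <- integer(config$n_psites)
    for (idx in split(seq_along(host), host))
      pos[idx] <- sample(2000L, length(idx))  # unique positions per protein
    site_id <- paste0(host, "_", residue, pos)
    loop_sites <- stats::setNames(
      as.list(site_id[seq(1L, n_fixed, by = 3L)]), kinases)
    # substrates: sites on non-kinase host proteins
    off_kinase <- which(!host %in% kinases)
    substrates <- stats::setNames(lapply(kinases, function(k) {
      site_id[sample(off_kinase, config$n_substrates_per_kinase)]
    }), kinases)
    list(host = host, site_id = site_id, loop_sites = loop_sites,
         substrates = substrates)
  })

  ## --- planted structure ----------------------------------------------------
  truth <- with_seed(child_seed(config$seed, 2L), {
    act_lines <- sample(lines, config$n_active_pairs)
    act_kin <- sample(kinases, config$n_active_pairs)
    active <- stats::setNames(as.list(act_kin), act_lines)
    drugs <- sprintf("DRUG%02d", seq_len(config$n_drugs))
    targets <- stats::setNames(
      lapply(seq_len(config$n_drugs),
             function(i) sample(kinases, sample(1:2, 1))), drugs)
    # guarantee each active kinase is hit by at least one drug
    for (i in seq_along(act_kin)) {
      dg <- drugs[(i - 1L) %% config$n_drugs + 1L]
      targets[[dg]] <- unique(c(targets[[dg]], act_kin[i]))
    }
    # the last drug is cell-cycle linked: sensitive exactly in lines whose
    # dominant periodic cluster is cluster 2 (S-phase-like)
    cc_drug <- drugs[config$n_drugs]
    targets[[cc_drug]] <- character()
    dominant <- stats::setNames(((seq_along(lines) - 1L) %% 5L) + 1L, lines)
    list(active_kinases = active, drugs = drugs, drug_targets = targets,
         cc_drug = cc_drug, periodic_profile = dominant)
  })

  ## --- periodic clusters ----------------------------------------------------
  clusters <- with_seed(child_seed(config$seed, 3L), {
    n_per <- config$n_periodic_proteins
    members <- sample(others, n_per)
    stats::setNames(split(members, rep_len(1:5, n_per)), as.character(1:5))
  })

  annotations <- annotation_set(
    kinase_ids = kinases,
    druggable_kinases = sort(unique(unlist(truth$drug_targets))),
    activation_loop_sites = layout$loop_sites,
    substrate_sites = layout$substrates,
    periodic_clusters = clusters)

  ## --- true dose-response curves and AUC ------------------------------------
  # sensitisation scales with the molecular effect so that a zero planted
  # effect carries no phenotypic consequence
  sens_fold <- config$ed50_sensitization ^
    (config$active_effect_log10 / 0.7)
  curves <- with_seed(child_seed(config$seed, 4L), {
    base_e <- stats::setNames(10^stats::rnorm(config$n_drugs, 2.7, 0.3),
                              truth$drugs)
    grid <- expand.grid(drug = truth$drugs, cell_line = lines,
                        stringsAsFactors = FALSE)
    grid$b <- 1.5; grid$c <- 0.05; grid$d <- 1
    grid$e <- vapply(seq_len(nrow(grid)), function(i) {
      dg <- grid$drug[i]; cl <- grid$cell_line[i]
      e <- base_e[[dg]]
      if (dg == truth$cc_drug) {
        if (truth$periodic_profile[[cl]] == 2L) e <- e / 100
      } else {
        hit <- length(intersect(truth$drug_targets[[dg]],
                                truth$active_kinases[[cl]])) > 0
        if (hit) e <- e / sens_fold
      }
      e
    }, numeric(1))
    grid
  })
  true_auc <- matrix(NA_real_, config$n_drugs, length(lines),
                     dimnames = list(truth$drugs, lines))
  rng <- range(config$doses)
  for (i in seq_len(nrow(curves))) {
    fit <- structure(list(b = curves$b[i], c = curves$c[i], d = curves$d[i],
                          e = curves$e[i], converged = TRUE,
                          doses = config$doses),
                     class = "curve_fit")
    true_auc[curves$drug[i], curves$cell_line[i]] <-
      standardized_auc(fit, rng)
  }

  ## --- proteome --------------------------------------------------------------
  proteome_log <- with_seed(child_seed(config$seed, 5L), {
    base <- stats::rnorm(config$n_proteins, 6, 0.8)
    m <- matrix(stats::rnorm(config$n_proteins * length(lines),
                             mean = base, sd = config$noise_sd_log10),
                config$n_proteins, length(lines),
                dimnames = list(proteins, lines))
    for (cl in names(truth$active_kinases))
      m[truth$active_kinases[[cl]], cl] <-
        m[truth$active_kinases[[cl]], cl] + config$active_effect_log10
    for (cl in lines) {
      dom <- as.character(truth$periodic_profile[[cl]])
      m[clusters[[dom]], cl] <- m[clusters[[dom]], cl] +
        config$periodic_effect_log10
    }
    m
  })

  ## --- planted marker links --------------------------------------------------
  marker_links <- with_seed(child_seed(config$seed, 6L), {
    eligible_feats <- setdiff(others, unlist(clusters))
    # link markers to drugs whose AUC actually varies across the panel
    var_drugs <- rownames(true_auc)[apply(true_auc, 1L, stats::sd) > 0.02]
    if (length(var_drugs) == 0L || config$n_marker_links == 0L) {
      data.frame(feature = character(), drug = character(),
                 slope_sign = integer(), stringsAsFactors = FALSE)
    } else {
      feats <- sample(eligible_feats, config$n_marker_links)
      dgs <- sample(var_drugs, config$n_marker_links, replace = TRUE)
      sign <- rep_len(c(-1L, 1L), config$n_marker_links)
      for (i in seq_len(config$n_marker_links)) {
        a <- true_auc[dgs[i], ]
        z <- (a - mean(a)) / stats::sd(a)
        proteome_log[feats[i], ] <- 6 + sign[i] * z +
          stats::rnorm(length(lines), 0, 0.1)
      }
      data.frame(feature = feats, drug = dgs, slope_sign = sign,
                 stringsAsFactors = FALSE)
    }
  })

  ## --- phosphoproteome -------------------------------------------------------
  phospho_log <- with_seed(child_seed(config$seed, 7L), {
    base <- stats::rnorm(config$n_psites, 5, 0.8)
    m <- matrix(stats::rnorm(config$n_psites * length(lines),
                             mean = base, sd = config$noise_sd_log10),
                config$n_psites, length(lines),
                dimnames = list(layout$site_id, lines))
    for (cl in names(truth$active_kinases)) {
      k <- truth$active_kinases[[cl]]
      boosted <- unique(c(layout$site_id[layout$host %in% k],
                          unlist(layout$loop_sites[k]),
                          unlist(layout$substrates[k])))
      m[boosted, cl] <- m[boosted, cl] + config$active_effect_log10
    }
    m
  })

  ## --- missingness -----------------------------------------------------------
  apply_missing <- function(m, sub) {
    if (config$missing_rate == 0) return(m)
    with_seed(child_seed(config$seed, sub), {
      m[stats::runif(length(m)) < config$missing_rate] <- NA_real_
      m
    })
  }
  complete_proteome <- proteome_log
  proteome_log <- apply_missing(proteome_log, 8L)
  phospho_log <- apply_missing(phospho_log, 9L)
  # planted kinase-abundance cells are never masked: the activity landscape
  # requires proteome evidence as a hard gate, and the recovery tests are
  # meant to measure the method, not the missingness mask; all other planted
  # evidence is redundant across several sites and stays maskable
  for (cl in names(truth$active_kinases))
    proteome_log[truth$active_kinases[[cl]], cl] <-
      complete_proteome[truth$active_kinases[[cl]], cl]

  ## --- drug screen wells ------------------------------------------------------
  mu_neg <- 1e5; mu_pos <- 2e3
  sig_sd <- config$signal_noise_frac * mu_neg
  screen <- with_seed(child_seed(config$seed, 10L), {
    rows <- list()
    for (cl in lines) {
      sub <- curves[curves$cell_line == cl, , drop = FALSE]
      v <- do.call(rbind, lapply(seq_len(nrow(sub)), function(i) {
        expand.grid(drug = sub$drug[i], cell_line = cl,
                    dose_uM = config$doses, replicate = 1:3,
                    stringsAsFactors = FALSE)
      }))
      key <- match(v$drug, sub$drug)
      via <- fourpl(v$dose_uM, sub$b[key], sub$c[key], sub$d[key],
                    sub$e[key])
      v$signal <- mu_pos + via * (mu_neg - mu_pos) +
        stats::rnorm(nrow(v), 0, sig_sd)
      v$well_role <- "sample"
      ctrl <- data.frame(
        drug = rep(c("DMSO", "STAUROSPORINE"), each = 12L),
        cell_line = cl,
        dose_uM = rep(c(0, 5), each = 12L),
        replicate = rep(1:12, 2L),
        signal = c(stats::rnorm(12, mu_neg, sig_sd),
                   stats::rnorm(12, mu_pos, sig_sd)),
        well_role = rep(c("negative_control", "positive_control"),
                        each = 12L),
        stringsAsFactors = FALSE)
      rows[[cl]] <- rbind(v, ctrl)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })

  truth_out <- list(
    active_kinases = truth$active_kinases,
    drug_targets = truth$drug_targets,
    true_curves = curves,
    true_auc = true_auc,
    marker_links = marker_links,
    periodic_profile = truth$periodic_profile,
    cc_drug = truth$cc_drug)

  list(proteome = abundance_matrix(10^proteome_log, scale = "linear"),
       phospho = abundance_matrix(10^phospho_log, scale = "linear"),
       annotations = annotations,
       screen = screen,
       truth = truth_out)
}

#' Generate a synthetic treatment time course
#'
#' Reporter matrices (features x time channels) for a treated and a vehicle
#' arm over the canonical grid `{0, 5, 10, 15, 30, 90, 180, 360, 720, 1440}`
#' minutes. Regulated features follow an exponential approach to a planted
#' plateau log2 fold change in the treated arm only
#' (`log2 ratio(t) = plateau * (1 - exp(-t / tau))`); the vehicle arm is flat
#' up to noise.
#'
#' @param n_features number of features (default 200).
#' @param n_regulated number of planted regulated features (default 30).
#' @param noise_sd_log2 per-channel log2 noise SD (default 0.1).
#' @param plateau_range absolute planted plateau range on the log2 scale
#'   (default `c(1.5, 3)`, i.e. roughly 3- to 8-fold).
#' @param seed integer seed.
#' @return list with `treated` and `vehicle` matrices (linear intensities),
#'   `time_min`, and `truth` (data.frame: feature, direction, plateau_log2,
#'   tau_min).
#' @export
generate_timecourse <- function(n_features = 200, n_regulated = 30,
                                noise_sd_log2 = 0.1,
                                plateau_range = c(1.5, 3), seed = 1) {
  stopifnot(n_regulated <= n_features)
  time_min <- c(0, 5, 10, 15, 30, 90, 180, 360, 720, 1440)
  with_seed(seed, {
    feats <- sprintf("PEP%04d", seq_len(n_features))
    base <- 10^stats::rnorm(n_features, 5, 0.6)
    reg <- sort(sample(n_features, n_regulated))
    dir <- sample(c(-1, 1), n_regulated, replace = TRUE)
    plateau <- dir * stats::runif(n_regulated, plateau_range[1L],
                                  plateau_range[2L])
    tau <- stats::runif(n_regulated, 20, 120)
    l2 <- matrix(0, n_features, length(time_min),
                 dimnames = list(feats, as.character(time_min)))
    for (i in seq_along(reg))
      l2[reg[i], ] <- plateau[i] * (1 - exp(-time_min / tau[i]))
    noise <- function() matrix(stats::rnorm(length(l2), 0, noise_sd_log2),
                               nrow(l2), ncol(l2))
    treated <- base * 2^(l2 + noise())
    vehicle <- base * 2^noise()
    dimnames(treated) <- dimnames(vehicle) <- dimnames(l2)
    list(treated = treated, vehicle = vehicle, time_min = time_min,
         truth = data.frame(feature = feats[reg],
                            direction = ifelse(dir > 0, "up", "down"),
                            plateau_log2 = plateau, tau_min = tau,
                            stringsAsFactors = FALSE))
  })
}

#' Serialise / restore a planted-truth record
#'
#' The planted truth travels as structured JSON text so downstream recovery
#' tests can be run against regenerated or archived panels.
#'
#' @param truth the `truth` element of [generate_panel()].
#' @param path output path.
#' @return `path` (writer) / the truth list (reader).
#' @export
write_planted_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_planted_truth
#' @export
read_planted_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
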