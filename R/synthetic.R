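#' Simulation configuration
#'
#' Validated parameter bundle for the metabolomics / lipidomics simulators.
#' Intensities follow a log-normal model: per-feature baseline log2
#' abundances with additive group shifts (the planted effects) and Gaussian
#' noise on the log2 scale. Missingness is left-censored at a per-feature
#' low quantile, mimicking detection limits.
#'
#' @param n_samples_per_group samples per group (two groups are generated).
#' @param n_subpathways number of subpathways (>= number of planted ones).
#' @param metabolites_per_subpathway features per subpathway, >= 3.
#' @param planted_effects named list: subpathway -> list(direction, effect)
#'   with direction in {up, down, null} and effect >= 0 in log2 units.
#' @param noise_sd residual SD on the log2 scale (default 1).
#' @param missing_fraction left-censored missing fraction in `[0, 1)`.
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples_per_group = 10, n_subpathways = 12,
                       metabolites_per_subpathway = 5,
                       planted_effects = list(), noise_sd = 1,
                       missing_fraction = 0, seed = 1) {
  if (n_samples_per_group < 2) stop("invalid config: n_samples_per_group must be >= 2")
  if (metabolites_per_subpathway < 3)
    stop("invalid config: metabolites_per_subpathway must be >= 3")
  if (n_subpathways < max(1, length(planted_effects)))
    stop("invalid config: n_subpathways smaller than the number of planted subpathways")
  if (missing_fraction < 0 || missing_fraction >= 1)
    stop("invalid config: missing_fraction must lie in [0, 1)")
  if (noise_sd <= 0) stop("invalid config: noise_sd must be positive")
  for (nm in names(planted_effects)) {
    pe <- planted_effects[[nm]]
    if (!is.list(pe) || is.null(pe$direction) || is.null(pe$effect))
      stop("invalid config: planted_effects[['", nm, "']] needs direction and effect")
    if (!pe$direction %in% c("up", "down", "null"))
      stop("invalid config: planted_effects[['", nm, "']] direction must be up/down/null")
    if (pe$effect < 0)
      stop("invalid config: planted_effects[['", nm, "']] effect must be >= 0")
  }
  structure(
    list(n_samples_per_group = as.integer(n_samples_per_group),
         n_subpathways = as.integer(n_subpathways),
         metabolites_per_subpathway = as.integer(metabolites_per_subpathway),
         planted_effects = planted_effects, noise_sd = noise_sd,
         missing_fraction = missing_fraction, seed = as.integer(seed)),
    class = "sim_config"
  )
}

SUPER_PATHWAY_POOL <- c("Lipid", "Amino Acid", "Carbohydrate", "Nucleotide", "Cofactor")

signed_effect <- function(pe) {
  if (is.null(pe) || pe$direction == "null") 0 else
    if (pe$direction == "up") pe$effect else -pe$effect
}

censor_low <- function(m, fraction) {
  if (fraction <= 0) return(m)
  for (j in seq_len(ncol(m))) {
    cut <- stats::quantile(m[, j], fraction, na.rm = TRUE)
    m[m[, j] <= cut, j] <- NA
  }
  m
}

#' Simulate a two-group metabolomics experiment
#'
#' Log-normal intensities with subpathway structure: every feature gets a
#' baseline log2 abundance; features in planted subpathways are shifted by
#' the configured effect (log2 units) in group2. Returns the raw-scale
#' matrix, the subpathway annotation and the planted ground truth. Output
#' is fully determined by the config seed.
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (raw-unit [feature_matrix()], groups `group1`
#'   and `group2` in the metadata), `annotation` ([pathway_annotation()]),
#'   `truth` (data.frame sub_pathway, direction, effect).
#' @export
simulate_metabolomics <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  planted <- names(config$planted_effects)
  n_fill <- config$n_subpathways - length(planted)
  sp_names <- c(planted, sprintf("SP%02d", seq_len(n_fill)))
  m_per <- config$metabolites_per_subpathway
  n <- config$n_samples_per_group
  feats <- unlist(lapply(sp_names, function(sp)
    paste0("met_", sp, "_", seq_len(m_per))))
  ann <- pathway_annotation(
    feature_id = feats,
    super_pathway = rep(SUPER_PATHWAY_POOL[(seq_along(sp_names) - 1) %%
                                             length(SUPER_PATHWAY_POOL) + 1], each = m_per),
    sub_pathway = rep(sp_names, each = m_per)
  )
  shift <- rep(vapply(sp_names, function(sp)
    signed_effect(config$planted_effects[[sp]]), 1), each = m_per)

  vals <- withr::with_seed(config$seed, {
    baseline <- stats::rnorm(length(feats), mean = 20, sd = 2)
    lv <- matrix(stats::rnorm(2 * n * length(feats), sd = config$noise_sd),
                 nrow = 2 * n)
    lv <- sweep(lv, 2, baseline, "+")
    lv[(n + 1):(2 * n), ] <- sweep(lv[(n + 1):(2 * n), , drop = FALSE], 2, shift, "+")
    censor_low(2^lv, config$missing_fraction)
  })
  rownames(vals) <- c(paste0("g1_s", seq_len(n)), paste0("g2_s", seq_len(n)))
  colnames(vals) <- feats
  meta <- data.frame(group = rep(c("group1", "group2"), each = n),
                     row.names = rownames(vals))
  truth <- data.frame(
    sub_pathway = sp_names,
    direction = vapply(sp_names, function(sp) {
      pe <- config$planted_effects[[sp]]
      if (is.null(pe)) "null" else pe$direction
    }, ""),
    effect = vapply(sp_names, function(sp) {
      pe <- config$planted_effects[[sp]]
      if (is.null(pe)) 0 else pe$effect
    }, 1),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(matrix = feature_matrix(vals, meta, unit = "raw"),
       annotation = ann, truth = truth)
}

#' Simulate a two-group lipidomics experiment
#'
#' Emits a raw-unit intensity matrix whose feature ids are parseable lipid
#' names: for each lipid class, species are drawn as distinct chain
#' combinations from the chain pool. Planted classes are shifted in group2
#' as configured. Names and values are seed-deterministic.
#'
#' @param config a [sim_config()] (planted_effects keyed by lipid class,
#'   e.g. `"DG"`, `"TG"`; `n_subpathways` is the number of classes drawn
#'   from `classes`).
#' @param classes candidate lipid classes (must cover the planted ones).
#' @param chain_pool chains ("C:D") species are assembled from.
#' @return list with `matrix` (raw-unit [feature_matrix()]) and `truth`
#'   (data.frame feature_id, class_code, direction, effect).
#' @export
simulate_lipidomics <- function(config,
                                classes = c("DG", "TG", "PC", "PE", "PI", "PS",
                                            "CE", "SM", "PG", "PA", "lyso.PC",
                                            "plasmenyl.PE"),
                                chain_pool = c("14:0", "16:0", "16:1",
                                               "18:0", "18:1", "18:2")) {
  stopifnot(inherits(config, "sim_config"))
  planted <- names(config$planted_effects)
  if (!all(planted %in% classes))
    stop("invalid config: planted class not in `classes`: ",
         setdiff(planted, classes)[1])
  use_classes <- c(planted, setdiff(classes, planted))
  use_classes <- use_classes[seq_len(min(config$n_subpathways, length(use_classes)))]
  m_per <- config$metabolites_per_subpathway
  n <- config$n_samples_per_group

  res <- withr::with_seed(config$seed, {
    feats <- unlist(lapply(use_classes, function(cl) {
      arity <- LIPID_CLASS_ARITY[[cl]]
      combos <- do.call(expand.grid, c(rep(list(chain_pool), arity),
                                       stringsAsFactors = FALSE))
      if (nrow(combos) < m_per)
        stop("chain pool too small for ", m_per, " distinct ", cl, " species")
      pick <- combos[sample.int(nrow(combos), m_per), , drop = FALSE]
      apply(pick, 1, function(ch) paste0(cl, "(", paste(ch, collapse = "/"), ")"))
    }))
    shift <- rep(vapply(use_classes, function(cl)
      signed_effect(config$planted_effects[[cl]]), 1), each = m_per)
    baseline <- stats::rnorm(length(feats), mean = 18, sd = 2)
    lv <- matrix(stats::rnorm(2 * n * length(feats), sd = config$noise_sd),
                 nrow = 2 * n)
    lv <- sweep(lv, 2, baseline, "+")
    lv[(n + 1):(2 * n), ] <- sweep(lv[(n + 1):(2 * n), , drop = FALSE], 2, shift, "+")
    list(feats = feats, vals = censor_low(2^lv, config$missing_fraction))
  })
  vals <- res$vals
  rownames(vals) <- c(paste0("g1_s", seq_len(n)), paste0("g2_s", seq_len(n)))
  colnames(vals) <- res$feats
  meta <- data.frame(group = rep(c("group1", "group2"), each = n),
                     row.names = rownames(vals))
  cls <- rep(use_classes, each = m_per)
  truth <- data.frame(
    feature_id = res$feats,
    class_code = cls,
    direction = vapply(cls, function(cl) {
      pe <- config$planted_effects[[cl]]
      if (is.null(pe)) "null" else pe$direction
    }, ""),
    effect = vapply(cls, function(cl) {
      pe <- config$planted_effects[[cl]]
      if (is.null(pe)) 0 else pe$effect
    }, 1),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(matrix = feature_matrix(vals, meta, unit = "raw"), truth = truth)
}

#' Simulate an expression cohort with survival and an MNA label
#'
#' A latent per-patient activity variable drives the signature: up-genes
#' load positively (`effect` x latent), down-genes negatively; background
#' genes are pure noise. Survival times are exponential with a hazard
#' increasing in the latent activity, with uniform censoring; OS and EFS
#' endpoints are generated with different baseline rates. The MNA label
#' marks the top latent tertile, with a configurable misclassification
#' rate.
#'
#' @param n_patients cohort size.
#' @param signature list with disjoint non-empty `up` and `down` gene-name
#'   vectors.
#' @param effect latent-to-expression loading (log2 units per latent SD).
#' @param seed integer seed.
#' @param n_background number of unrelated noise genes (default 50).
#' @param base_hazard_os,base_hazard_efs baseline event rates per time unit.
#' @param hazard_beta log-hazard increase per latent SD (default 0.7).
#' @param censor_max uniform censoring horizon (default 10 time units).
#' @param mna_error MNA label flip probability (default 0.05).
#' @return list with `matrix` (log2-unit [feature_matrix()]), `clinical`
#'   (subject_id, mna, os_time, os_event, efs_time, efs_event), `latent`.
#' @export
simulate_expression_cohort <- function(n_patients, signature, effect, seed = 1,
                                       n_background = 50,
                                       base_hazard_os = 0.08,
                                       base_hazard_efs = 0.12,
                                       hazard_beta = 0.7,
                                       censor_max = 10, mna_error = 0.05) {
  up <- signature$up; down <- signature$down
  if (length(up) == 0 || length(down) == 0)
    stop("signature needs non-empty up and down gene lists")
  if (length(intersect(up, down)) > 0)
    stop("up and down gene lists overlap: ", intersect(up, down)[1])
  if (effect < 0) stop("effect must be >= 0")
  genes <- c(up, down, sprintf("BG%03d", seq_len(n_background)))

  withr::with_seed(seed, {
    latent <- stats::rnorm(n_patients)
    loading <- c(rep(effect, length(up)), rep(-effect, length(down)),
                 rep(0, n_background))
    expr <- outer(latent, loading) +
      matrix(stats::rnorm(n_patients * length(genes)), nrow = n_patients)
    rownames(expr) <- sprintf("pt%04d", seq_len(n_patients))
    colnames(expr) <- genes

    surv_endpoint <- function(base) {
      t_event <- stats::rexp(n_patients, rate = base * exp(hazard_beta * latent))
      t_cens <- stats::runif(n_patients, 0, censor_max)
      time <- pmin(t_event, t_cens)
      time <- pmax(time, 1e-6)
      list(time = time, event = as.integer(t_event <= t_cens))
    }
    os <- surv_endpoint(base_hazard_os)
    efs <- surv_endpoint(base_hazard_efs)

    mna <- latent > stats::quantile(latent, 2 / 3)
    flip <- stats::runif(n_patients) < mna_error
    mna[flip] <- !mna[flip]

    clinical <- data.frame(
      subject_id = rownames(expr),
      mna = mna,
      os_time = os$time, os_event = os$event,
      efs_time = efs$time, efs_event = efs$event,
      stringsAsFactors = FALSE
    )
    meta <- data.frame(group = ifelse(mna, "MNA", "non-MNA"),
                       row.names = rownames(expr))
    list(matrix = feature_matrix(expr, meta, unit = "log2"),
         clinical = clinical, latent = latent)
  })
}

#' Simulate a replicated two-drug viability grid
#'
#' Single-agent inhibition follows a monotone saturating dose curve
#' (half-maximal at the largest tested dose, so margins stay below 50%
#' inhibition and Bliss expectations stay clear of the 100% ceiling).
#' Combination cells equal the Bliss-independence expectation plus the
#' configured excess (percentage points; positive for `synergistic`,
#' negative for `antagonistic`, zero for `bliss-independent`) plus noise.
#' Every replicate is renormalized to its untreated (0, 0) well, so that
#' anchor cell is exactly 100.
#'
#' @param doses_a,doses_b positive dose levels (dose 0 margins are added).
#' @param model interaction model.
#' @param excess planted mean Bliss excess in percentage points (>= 0; the
#'   sign comes from `model`).
#' @param reps replicates (>= 1).
#' @param noise_sd viability noise SD in percent (default 0).
#' @param seed integer seed.
#' @return long-format data.frame `dose_a`, `dose_b`, `replicate`,
#'   `viability`; attributes `model` and `planted_excess` record the truth.
#' @export
simulate_dose_grid <- function(doses_a, doses_b,
                               model = c("bliss-independent", "synergistic",
                                         "antagonistic"),
                               excess = 0, reps = 3, noise_sd = 0, seed = 1) {
  model <- match.arg(model)
  if (any(doses_a <= 0) || any(doses_b <= 0)) stop("doses must be positive")
  if (reps < 1) stop("reps must be >= 1")
  if (excess < 0) stop("excess must be >= 0 (sign comes from `model`)")
  signed_excess <- switch(model, `bliss-independent` = 0,
                          synergistic = excess, antagonistic = -excess)
  hill <- function(d, ec50) d / (d + ec50)
  ia <- c(0, hill(doses_a, max(doses_a)))
  ib <- c(0, hill(doses_b, max(doses_b)))
  da <- c(0, doses_a); db <- c(0, doses_b)

  grid <- expand.grid(ai = seq_along(da), bi = seq_along(db),
                      replicate = seq_len(reps))
  inh <- ia[grid$ai] + ib[grid$bi] - ia[grid$ai] * ib[grid$bi]
  combo <- da[grid$ai] > 0 & db[grid$bi] > 0
  inh[combo] <- inh[combo] + signed_excess / 100
  viab <- 100 * (1 - inh)

  out <- withr::with_seed(seed, {
    anchor <- da[grid$ai] == 0 & db[grid$bi] == 0
    if (noise_sd > 0)
      viab[!anchor] <- viab[!anchor] + stats::rnorm(sum(!anchor), sd = noise_sd)
    viab <- pmax(viab, 0)
    # renormalize each replicate to its untreated well
    for (r in seq_len(reps)) {
      sel <- grid$replicate == r
      v00 <- viab[sel & anchor]
      viab[sel] <- viab[sel] / v00 * 100
    }
    data.frame(dose_a = da[grid$ai], dose_b = db[grid$bi],
               replicate = grid$replicate, viability = viab)
  })
  attr(out, "model") <- model
  attr(out, "planted_excess") <- signed_excess
  out
}
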