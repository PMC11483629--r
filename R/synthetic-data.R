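#' Configuration for the synthetic study-design generator
#'
#' Describes a multi-tissue, multi-stage bulk RNA-seq experiment on a
#' storage-root-forming plant: five tissues sampled at three developmental
#' stages of root bulking (pre-bulking PB, early-bulking EB, during-bulking
#' DB), with negative-binomial counts, library-size variation, and planted
#' co-expressed gene modules whose expected expression follows one of four
#' stage-profile templates (monotone up, monotone down, EB peak, EB dip).
#'
#' @param n_genes Number of genes.
#' @param tissues Ordered tissue labels.
#' @param stages Ordered stage labels.
#' @param replicates_per_stage Replicate plants per tissue-stage combination.
#' @param baseline_logmean_params `c(meanlog, sdlog)` of the log-normal
#'   distribution of per-gene baseline mean counts.
#' @param dispersion_params `c(meanlog, sdlog)` of the log-normal distribution
#'   of per-gene NB dispersions (variance = mu + alpha * mu^2).
#' @param size_factor_range Positive interval from which per-sample size
#'   factors are drawn log-uniformly (then rescaled to geometric mean 1).
#' @param modules_per_tissue Number of planted co-expression modules per
#'   tissue.
#' @param module_size Genes per module. Module gene sets are disjoint within
#'   a tissue but drawn independently across tissues.
#' @param module_fold_change Ratio (> 0) between the highest and lowest stage
#'   multiplier of a module template; 1 gives flat templates (no true DEGs).
#' @param profile_templates Optional named list of stage-multiplier vectors
#'   (length `length(stages)`, strictly positive). Defaults to the four
#'   qualitative shapes `up`, `down`, `eb_peak`, `eb_dip` built from
#'   `module_fold_change`; requires exactly 3 stages unless supplied.
#' @param batch_levels Number of experimental batches (2 emulates a storage
#'   root experiment reproduced in an independent sequencing run). Batches
#'   are assigned by replicate parity so batch and stage stay unconfounded.
#' @param batch_sd On the log scale, the SD of the per-gene multiplicative
#'   batch offset (shared by all samples of a batch).
#' @param analytes Phenotype analytes (non-structural carbohydrates),
#'   measured in mg per g dry weight.
#' @param gamma_shape Shape of the Gamma distribution used for phenotype
#'   values (larger = less dispersed).
#' @param phenotype_means Optional numeric array `tissue x stage x analyte` of
#'   true phenotype means; defaults to a built-in table emulating storage-root
#'   sugar/starch accumulation during bulking (see
#'   [default_phenotype_means()]).
#' @param naf_mean Simplex mean vector over subcellular compartments
#'   (vacuole, plastid, cytosol) for the non-aqueous fractionation table.
#' @param naf_concentration Dirichlet concentration (precision) for NAF
#'   replicate compositions.
#' @param naf_sugars Sugars measured in the NAF experiment.
#' @param naf_replicates Replicates per sugar in the NAF experiment.
#' @param seed Integer master seed; all generators are deterministic given
#'   the configuration.
#' @return A validated list of class `sim_config`.
#' @seealso [generate_counts()], [generate_phenotypes()], [generate_naf()]
#' @export
sim_config <- function(n_genes = 2000,
                       tissues = c("SoL", "Bark", "Wood", "FR", "SR"),
                       stages = c("PB", "EB", "DB"),
                       replicates_per_stage = 4,
                       baseline_logmean_params = c(log(100), 1.2),
                       dispersion_params = c(log(0.05), 0.5),
                       size_factor_range = c(0.5, 2.0),
                       modules_per_tissue = 4,
                       module_size = 100,
                       module_fold_change = 4,
                       profile_templates = NULL,
                       batch_levels = 1,
                       batch_sd = 0.5,
                       analytes = c("glucose", "fructose", "sucrose", "starch"),
                       gamma_shape = 10,
                       phenotype_means = NULL,
                       naf_mean = c(vacuole = 0.40, plastid = 0.35, cytosol = 0.25),
                       naf_concentration = 200,
                       naf_sugars = c("fructose", "glucose", "sucrose"),
                       naf_replicates = 7,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), tissues = tissues, stages = stages,
              replicates_per_stage = as.integer(replicates_per_stage),
              baseline_logmean_params = baseline_logmean_params,
              dispersion_params = dispersion_params,
              size_factor_range = size_factor_range,
              modules_per_tissue = as.integer(modules_per_tissue),
              module_size = as.integer(module_size),
              module_fold_change = module_fold_change,
              profile_templates = profile_templates,
              batch_levels = as.integer(batch_levels), batch_sd = batch_sd,
              analytes = analytes, gamma_shape = gamma_shape,
              phenotype_means = phenotype_means,
              naf_mean = naf_mean, naf_concentration = naf_concentration,
              naf_sugars = naf_sugars, naf_replicates = as.integer(naf_replicates),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1) abort_validation("n_genes must be positive")
  if (cfg$replicates_per_stage < 1) abort_validation("replicates_per_stage must be positive")
  if (length(cfg$tissues) < 1 || length(cfg$stages) < 2)
    abort_validation("need at least 1 tissue and 2 stages")
  if (any(cfg$size_factor_range <= 0) || diff(cfg$size_factor_range) < 0)
    abort_validation("size_factor_range must be a positive interval")
  if (cfg$module_fold_change <= 0)
    abort_validation("module_fold_change must be > 0")
  if (cfg$modules_per_tissue * cfg$module_size > cfg$n_genes)
    abort_validation("module definitions exceed n_genes: ",
                     cfg$modules_per_tissue, " x ", cfg$module_size,
                     " > ", cfg$n_genes)
  if (!is.null(cfg$profile_templates)) {
    ok <- vapply(cfg$profile_templates,
                 function(p) length(p) == length(cfg$stages) && all(p > 0),
                 logical(1))
    if (!all(ok))
      abort_validation("profile templates must be strictly positive vectors, one multiplier per stage")
  } else if (length(cfg$stages) != 3) {
    abort_validation("default profile templates require exactly 3 stages; supply profile_templates")
  }
  if (cfg$batch_levels < 1) abort_validation("batch_levels must be >= 1")
  if (cfg$gamma_shape <= 0) abort_validation("gamma_shape must be positive")
  if (abs(sum(cfg$naf_mean) - 1) > 1e-8 || any(cfg$naf_mean <= 0))
    abort_validation("naf_mean must lie on the open simplex (positive, summing to 1)")
  if (cfg$naf_concentration <= 0) abort_validation("naf_concentration must be positive")
  invisible(cfg)
}

# The four qualitative stage shapes, scaled to fold change f between the
# extreme stages with a geometric intermediate.
default_templates <- function(fold) {
  s <- sqrt(fold)
  list(up = c(1, s, fold), down = c(fold, s, 1),
       eb_peak = c(1, fold, 1), eb_dip = c(fold, 1, fold))
}

sim_templates <- function(cfg) {
  cfg$profile_templates %||% default_templates(cfg$module_fold_change)
}

#' Generate a synthetic count matrix with planted co-expression modules
#'
#' Draws NB-distributed counts `NB(mean = size_factor x baseline x stage
#' multiplier x batch offset, dispersion = per-gene alpha)`. Within each
#' tissue, `modules_per_tissue` disjoint gene modules share one stage-profile
#' template; all other (background) genes have flat stage profiles. Returns
#' the full ground truth needed for recovery tests.
#'
#' @param config A [sim_config()].
#' @return A list with elements `counts` (a [count_matrix()]) and `truth`, a
#'   list with `size_factors`, `baseline`, `dispersions`, `module_membership`
#'   (gene x tissue integer matrix, 0 = background), `deg_flags`
#'   (gene x tissue logical), `templates`, and `batch_offsets`.
#' @export
generate_counts <- function(config) {
  validate_sim_config(config)
  templates <- sim_templates(config)
  with_seed(derive_seed(config$seed, "counts"), {
    ng <- config$n_genes
    gene_ids <- sprintf("g%05d", seq_len(ng))
    meta <- expand.grid(replicate = seq_len(config$replicates_per_stage),
                        stage = config$stages, tissue = config$tissues,
                        stringsAsFactors = FALSE)
    meta <- meta[, c("tissue", "stage", "replicate")]
    meta$batch <- ((meta$replicate - 1L) %% config$batch_levels) + 1L
    meta$sample_id <- sprintf("%s_%s_R%d", meta$tissue, meta$stage, meta$replicate)
    ns <- nrow(meta)

    baseline <- rlnorm(ng, config$baseline_logmean_params[1],
                       config$baseline_logmean_params[2])
    alpha <- rlnorm(ng, config$dispersion_params[1], config$dispersion_params[2])
    sf <- exp(runif(ns, log(config$size_factor_range[1]),
                    log(config$size_factor_range[2])))
    sf <- sf / geomean(sf)
    names(sf) <- meta$sample_id

    # module membership: per tissue, disjoint modules sampled from the universe
    membership <- matrix(0L, ng, length(config$tissues),
                         dimnames = list(gene_ids, config$tissues))
    k <- config$modules_per_tissue
    for (t in config$tissues) {
      idx <- sample.int(ng, k * config$module_size)
      membership[idx, t] <- rep(seq_len(k), each = config$module_size)
    }

    # per-gene multiplicative batch offsets (log-normal, batch 1 = reference)
    batch_off <- matrix(1, ng, config$batch_levels)
    if (config$batch_levels > 1)
      for (b in 2:config$batch_levels)
        batch_off[, b] <- rlnorm(ng, 0, config$batch_sd)

    template_mat <- do.call(rbind, templates)  # template x stage
    flat <- !vapply(templates, function(p) diff(range(p)) > 0, logical(1))

    mu <- matrix(0, ng, ns, dimnames = list(gene_ids, meta$sample_id))
    stage_idx <- match(meta$stage, config$stages)
    tissue_idx <- match(meta$tissue, config$tissues)
    for (j in seq_len(ns)) {
      mod <- membership[, tissue_idx[j]]
      mult <- rep(1, ng)
      in_mod <- mod > 0L
      if (any(in_mod)) {
        tpl <- ((mod[in_mod] - 1L) %% length(templates)) + 1L
        mult[in_mod] <- template_mat[cbind(tpl, stage_idx[j])]
      }
      mu[, j] <- sf[j] * baseline * mult * batch_off[, meta$batch[j]]
    }
    counts <- matrix(rnbinom(ng * ns, mu = mu, size = rep(1 / alpha, ns)),
                     ng, ns, dimnames = dimnames(mu))

    deg_flags <- membership > 0L
    if (any(deg_flags)) {
      tpl_of <- ((membership - 1L) %% length(templates)) + 1L
      deg_flags[deg_flags] <- !flat[tpl_of[deg_flags]]
    }

    cm <- count_matrix(counts,
                       meta[, c("sample_id", "tissue", "stage", "batch", "replicate")],
                       tissue_levels = config$tissues,
                       stage_levels = config$stages)
    truth <- list(size_factors = sf, baseline = baseline, dispersions = alpha,
                  module_membership = membership, deg_flags = deg_flags,
                  templates = templates, batch_offsets = batch_off)
    list(counts = cm, truth = truth)
  })
}

#' Default true phenotype mean table
#'
#' Mean non-structural carbohydrate contents (mg per g dry weight) per tissue
#' and stage, emulating the qualitative pattern of storage-root bulking:
#' soluble sugars and starch rise strongly in the storage root during bulking,
#' stem wood starch declines as the storage root takes over, bark sucrose
#' declines slightly, and leaf/fibrous-root contents stay flat.
#'
#' @param tissues,stages,analytes Factor labels (defaults as in
#'   [sim_config()]).
#' @return A numeric array `tissue x stage x analyte` of strictly positive
#'   means.
#' @export
default_phenotype_means <- function(tissues = c("SoL", "Bark", "Wood", "FR", "SR"),
                                    stages = c("PB", "EB", "DB"),
                                    analytes = c("glucose", "fructose",
                                                 "sucrose", "starch")) {
  base <- c(glucose = 10, fructose = 8, sucrose = 30, starch = 50)
  m <- array(1, dim = c(length(tissues), length(stages), length(analytes)),
             dimnames = list(tissues, stages, analytes))
  for (a in analytes) m[, , a] <- base[[a]]
  n_st <- length(stages)
  ramp_up <- seq(1, 4, length.out = n_st)     # strong DB accumulation
  ramp_down <- seq(1.5, 0.5, length.out = n_st)
  if ("SR" %in% tissues) for (a in analytes)
    m["SR", , a] <- base[[a]] * ramp_up
  if ("Wood" %in% tissues && "starch" %in% analytes)
    m["Wood", , "starch"] <- base[["starch"]] * 1.6 * ramp_down
  if ("Bark" %in% tissues && "sucrose" %in% analytes)
    m["Bark", , "sucrose"] <- base[["sucrose"]] * seq(1.2, 0.8, length.out = n_st)
  if ("SoL" %in% tissues && "sucrose" %in% analytes)
    m["SoL", , "sucrose"] <- base[["sucrose"]] * 2.5  # high leaf sucrose, flat
  m
}

#' Generate a synthetic phenotype measurement table
#'
#' Values are drawn from a Gamma distribution with log-link mean structure:
#' per tissue x stage x analyte, mean given by the configured true mean table
#' and shape `gamma_shape`, with `replicates_per_stage` replicates.
#'
#' @param config A [sim_config()].
#' @return A list with `phenotypes` (data.frame of class `phenotype_table`
#'   with columns tissue, stage, replicate, analyte, value) and `truth`
#'   (list with `means` array and `shape`).
#' @export
generate_phenotypes <- function(config) {
  validate_sim_config(config)
  means <- config$phenotype_means %||%
    default_phenotype_means(config$tissues, config$stages, config$analytes)
  if (any(means <= 0)) abort_validation("phenotype means must be positive")
  with_seed(derive_seed(config$seed, "phenotypes"), {
    grid <- expand.grid(replicate = seq_len(config$replicates_per_stage),
                        stage = config$stages, tissue = config$tissues,
                        analyte = config$analytes, stringsAsFactors = FALSE)
    mu <- means[cbind(grid$tissue, grid$stage, grid$analyte)]
    shape <- config$gamma_shape
    grid$value <- rgamma(nrow(grid), shape = shape, rate = shape / mu)
    tab <- grid[, c("tissue", "stage", "replicate", "analyte", "value")]
    tab$tissue <- factor(tab$tissue, levels = config$tissues)
    tab$stage <- factor(tab$stage, levels = config$stages)
    class(tab) <- c("phenotype_table", "data.frame")
    list(phenotypes = tab, truth = list(means = means, shape = shape))
  })
}

#' Generate a synthetic subcellular compartment-fraction (NAF) table
#'
#' Per sugar, replicate compositions over the compartments (vacuole, plastid,
#' cytosol) are drawn from a Dirichlet distribution with the configured mean
#' and concentration; each replicate row sums to 1.
#'
#' @param config A [sim_config()].
#' @return A list with `naf` (data.frame of class `naf_table` with columns
#'   replicate, sugar, compartment, fraction) and `truth` (list with
#'   `proportions` and `concentration`).
#' @export
generate_naf <- function(config) {
  validate_sim_config(config)
  with_seed(derive_seed(config$seed, "naf"), {
    comp <- names(config$naf_mean)
    rows <- vector("list", length(config$naf_sugars))
    for (s in seq_along(config$naf_sugars)) {
      g <- matrix(rgamma(config$naf_replicates * length(comp),
                         shape = rep(config$naf_mean * config$naf_concentration,
                                     each = config$naf_replicates)),
                  config$naf_replicates, length(comp))
      frac <- g / rowSums(g)
      rows[[s]] <- data.frame(replicate = rep(seq_len(config$naf_replicates),
                                              times = length(comp)),
                              sugar = config$naf_sugars[s],
                              compartment = rep(comp, each = config$naf_replicates),
                              fraction = as.vector(frac))
    }
    tab <- do.call(rbind, rows)
    tab$compartment <- factor(tab$compartment, levels = comp)
    class(tab) <- c("naf_table", "data.frame")
    list(naf = tab, truth = list(proportions = config$naf_mean,
                                 concentration = config$naf_concentration))
  })
}
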