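#' Configuration for the synthetic tumor-microenvironment generators
#'
#' The generators emulate the statistical structure the deconvolution method
#' assumes: per-cell-class discriminative CpG blocks, extreme tumor-vs-normal
#' differential CpGs, truncated-Gaussian measurement noise on the beta scale,
#' and hierarchically Dirichlet-distributed mixing proportions with known
#' ground truth. All randomness is a pure function of `seed`.
#'
#' Defaults, chosen once to reflect a realistic desk-scale study:
#' * `n_probes = 12000`: enough for 17 x 100 private marker CpGs plus an
#'   abundant iDMC block and non-informative background.
#' * `markers_per_class = 100`: matches the per-class library size, half
#'   displaced up and half down so both marker directions exist. Each
#'   terminal class gets a private block, and each multi-leaf lineage node
#'   (Immune, Lymphoid, Myeloid, ...) gets a shared block carried by all its
#'   terminal classes, emulating lineage-wide methylation signatures.
#' * `delta = 0.3`: typical beta-scale separation of sorted-cell marker CpGs.
#' * `n_differential = 5000` tumor-vs-normal CpGs, hypermethylated half
#'   rising from the unmethylated noise floor (`idmc_low = 0.005`) toward
#'   the methylated ceiling (`idmc_high = 0.995`), hypomethylated half the
#'   mirror image -- iDMCs are by construction the extreme tail of the
#'   differential landscape (near-binary CpGs), which is what makes the
#'   density mode track purity.
#' * `noise_sd = 0.03`: Infinium-scale technical noise.
#' * `tumor_extra_sd = 0.08` at differential probes only, so the
#'   tumor-variance filter (`> 0.005`) separates differential from
#'   background probes.
#' * `purity_range = c(0.4, 0.95)`: purities of bulk tumor training samples.
#' * `concentration = 2`: symmetric Dirichlet parameter applied at every
#'   tree node when drawing mixture proportions top-down.
#' * `n_per_class = 6` reference replicates, `n_tumor = n_normal = 20`
#'   training samples, `n_mixtures = 50`.
#'
#' @param n_probes,markers_per_class,delta,n_differential,idmc_low,idmc_high
#'   See above.
#' @param noise_sd,tumor_extra_sd,purity_range,concentration See above.
#' @param n_per_class,n_tumor,n_normal,n_mixtures Sample counts.
#' @param tree Cell-lineage hierarchy, default [tme_hierarchy()]; pruned
#'   subtrees are honored by every generator.
#' @param seed Integer seed (default 17, the leaf count).
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_probes = 12000,
                              markers_per_class = 100,
                              delta = 0.3,
                              n_differential = 5000,
                              idmc_low = 0.005,
                              idmc_high = 0.995,
                              noise_sd = 0.03,
                              tumor_extra_sd = 0.08,
                              purity_range = c(0.4, 0.95),
                              concentration = 2,
                              n_per_class = 6,
                              n_tumor = 20,
                              n_normal = 20,
                              n_mixtures = 50,
                              tree = tme_hierarchy(),
                              seed = 17) {
  cfg <- list(
    n_probes = n_probes, markers_per_class = markers_per_class,
    delta = delta, n_differential = n_differential,
    idmc_low = idmc_low, idmc_high = idmc_high,
    noise_sd = noise_sd, tumor_extra_sd = tumor_extra_sd,
    purity_range = purity_range, concentration = concentration,
    n_per_class = n_per_class, n_tumor = n_tumor, n_normal = n_normal,
    n_mixtures = n_mixtures, tree = tree, seed = as.integer(seed)
  )
  if (!(cfg$delta > 0 || cfg$delta == 0) || cfg$delta > 1) {
    abort("delta must be in [0, 1]")
  }
  if (cfg$noise_sd < 0) abort("noise_sd must be >= 0")
  counts <- c(cfg$n_probes, cfg$markers_per_class, cfg$n_per_class,
              cfg$n_tumor, cfg$n_normal, cfg$n_mixtures)
  if (any(counts < 1)) abort("all counts must be >= 1")
  n_cell <- length(setdiff(tree$leaves, "Tumor"))
  internal <- setdiff(unique(tree$edges$parent), c("TME", "Nontumor"))
  n_internal <- sum(vapply(internal, function(nd) {
    length(intersect(hierarchy_leaves_under(tree, nd),
                     setdiff(tree$leaves, "Tumor"))) > 1
  }, TRUE))
  need <- (n_cell + n_internal) * cfg$markers_per_class + cfg$n_differential
  if (cfg$n_probes < need) {
    abort(sprintf(
      "n_probes (%d) < (leaf + lineage classes) x markers_per_class + n_differential (%d)",
      cfg$n_probes, need
    ))
  }
  structure(cfg, class = "sim_config")
}

# truncated additive Gaussian noise, clipped to [0, 1]
.add_noise <- function(x, sd) {
  if (sd <= 0) return(x)
  pmin(pmax(x + rnorm(length(x), 0, sd), 0), 1)
}

#' Latent class archetypes shared by all generators
#'
#' Deterministic in `cfg$seed`: a shared baseline beta vector, one archetype
#' per non-tumor terminal class (its private marker block displaced +/-
#' `delta`), a normal-tissue archetype (the baseline), and a tumor archetype
#' displaced at the differential block. Public generators reuse these so
#' panel, training and mixture data live in one consistent probe universe.
#'
#' @param cfg A [simulation_config()].
#' @return List with `probes`, `baseline`, `archetypes` (probe x class
#'   matrix, non-tumor classes), `tumor_archetype`, `normal_archetype`,
#'   `differential_probes` (tibble `probe`, `direction`), `marker_blocks`
#'   (named list class -> probe IDs).
#' @export
simulate_archetypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  tree <- cfg$tree
  cell_classes <- setdiff(tree$leaves, "Tumor")
  probes <- sprintf("cg%07d", seq_len(cfg$n_probes))

  withr_seed <- cfg$seed
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(withr_seed)

  baseline <- runif(cfg$n_probes, 0.1, 0.9)
  names(baseline) <- probes

  # reserve probe blocks: per-class markers first, then the differential block
  idx <- 1L
  marker_blocks <- list()
  arch <- matrix(baseline, nrow = cfg$n_probes, ncol = length(cell_classes),
                 dimnames = list(probes, cell_classes))
  half <- floor(cfg$markers_per_class / 2)
  for (cl in cell_classes) {
    block <- idx:(idx + cfg$markers_per_class - 1L)
    idx <- idx + cfg$markers_per_class
    marker_blocks[[cl]] <- probes[block]
    up <- block[seq_len(half)]
    down <- block[(half + 1L):length(block)]
    arch[up, cl] <- pmin(arch[up, cl] + cfg$delta, 0.98)
    arch[down, cl] <- pmax(arch[down, cl] - cfg$delta, 0.02)
  }

  # lineage-shared blocks: every terminal class under an internal node
  # carries the node's signature (real leukocyte lineages share methylation
  # signatures; without this, coarse layers are only weakly identifiable)
  internal <- setdiff(unique(tree$edges$parent), c("TME", "Nontumor"))
  internal <- internal[vapply(internal, function(nd) {
    length(intersect(hierarchy_leaves_under(tree, nd), cell_classes)) > 1
  }, TRUE)]
  for (nd in internal) {
    block <- idx:(idx + cfg$markers_per_class - 1L)
    idx <- idx + cfg$markers_per_class
    marker_blocks[[nd]] <- probes[block]
    up <- block[seq_len(half)]
    down <- block[(half + 1L):length(block)]
    under <- intersect(hierarchy_leaves_under(tree, nd), cell_classes)
    arch[up, under] <- pmin(arch[up, under] + cfg$delta, 0.98)
    arch[down, under] <- pmax(arch[down, under] - cfg$delta, 0.02)
  }

  diff_block <- idx:(idx + cfg$n_differential - 1L)
  diff_probes <- probes[diff_block]
  n_hyper <- floor(cfg$n_differential / 2)
  hyper <- diff_block[seq_len(n_hyper)]
  hypo <- setdiff(diff_block, hyper)

  normal_archetype <- baseline
  # differential probes sit at extreme baseline so the transformed mixture
  # betas track purity (hyper: low in normal, high in tumor; hypo mirrored)
  normal_archetype[hyper] <- runif(length(hyper), cfg$idmc_low,
                                   cfg$idmc_low + 0.005)
  normal_archetype[hypo] <- runif(length(hypo), cfg$idmc_high - 0.005,
                                  cfg$idmc_high)
  # tumor-normal separation at differential probes: iDMCs are the extreme
  # tail of the differential landscape, saturating the beta dynamic range
  # for any realistic marker separation (and vanishing with delta = 0)
  idmc_delta <- min(4 * cfg$delta, cfg$idmc_high - cfg$idmc_low)
  tumor_archetype <- normal_archetype
  tumor_archetype[hyper] <- pmin(normal_archetype[hyper] + idmc_delta,
                                 cfg$idmc_high)
  tumor_archetype[hypo] <- pmax(normal_archetype[hypo] - idmc_delta,
                                cfg$idmc_low)
  # cell archetypes share the extreme baseline at differential probes
  arch[diff_block, ] <- normal_archetype[diff_block]

  list(
    probes = probes,
    baseline = baseline,
    archetypes = arch,
    tumor_archetype = tumor_archetype,
    normal_archetype = normal_archetype,
    differential_probes = tibble::tibble(
      probe = diff_probes,
      direction = ifelse(diff_block %in% hyper, "hyper", "hypo")
    ),
    marker_blocks = marker_blocks
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate a purified-cell reference panel
#'
#' Each non-tumor terminal class contributes `n_per_class` replicate samples:
#' archetype plus truncated Gaussian noise.
#'
#' @param cfg A [simulation_config()].
#' @return List with `panel` (a [reference_panel()]), `archetypes` (the
#'   [simulate_archetypes()] list), and `config`.
#' @export
simulate_reference_panel <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  arch <- simulate_archetypes(cfg)
  classes <- colnames(arch$archetypes)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed + 1L)

  betas <- do.call(cbind, lapply(classes, function(cl) {
    m <- replicate(cfg$n_per_class, .add_noise(arch$archetypes[, cl],
                                               cfg$noise_sd))
    colnames(m) <- sprintf("%s_%02d", cl, seq_len(cfg$n_per_class))
    m
  }))
  rownames(betas) <- arch$probes
  labels <- setNames(rep(classes, each = cfg$n_per_class), colnames(betas))
  list(
    panel = reference_panel(betas, labels),
    archetypes = arch,
    config = cfg
  )
}

#' Simulate tumor and matched-normal training beta matrices
#'
#' Normal samples are the normal-tissue archetype plus noise. Tumor samples
#' are purity-weighted blends of the tumor and normal archetypes (purity
#' drawn uniformly from `cfg$purity_range`), with extra between-sample noise
#' at the differential probes so the tumor-variance filter has signal to
#' work with on both sides.
#'
#' @param cfg A [simulation_config()].
#' @return List with `tumor`, `normal` (beta matrices),
#'   `differential_probes` (tibble `probe`, `direction`), `purity` (named
#'   vector of the tumor samples' simulated purities), `archetypes`,
#'   `config`.
#' @export
simulate_tumor_normal <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  arch <- simulate_archetypes(cfg)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed + 2L)

  normal <- replicate(cfg$n_normal, .add_noise(arch$normal_archetype,
                                               cfg$noise_sd))
  dimnames(normal) <- list(arch$probes,
                           sprintf("normal_%02d", seq_len(cfg$n_normal)))

  pur <- runif(cfg$n_tumor, cfg$purity_range[1], cfg$purity_range[2])
  names(pur) <- sprintf("tumor_%02d", seq_len(cfg$n_tumor))
  diff_idx <- match(arch$differential_probes$probe, arch$probes)
  tumor <- vapply(seq_len(cfg$n_tumor), function(i) {
    x <- pur[i] * arch$tumor_archetype + (1 - pur[i]) * arch$normal_archetype
    x[diff_idx] <- .add_noise(x[diff_idx], cfg$tumor_extra_sd)
    .add_noise(x, cfg$noise_sd)
  }, numeric(cfg$n_probes))
  dimnames(tumor) <- list(arch$probes, names(pur))

  list(
    tumor = beta_matrix(tumor),
    normal = beta_matrix(normal),
    differential_probes = arch$differential_probes,
    purity = pur,
    archetypes = arch,
    config = cfg
  )
}

# one draw from Dirichlet(alpha) via gammas
.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

#' Simulate bulk mixtures with known ground truth
#'
#' Per sample, terminal-class proportions are drawn hierarchically: one
#' symmetric Dirichlet draw at every internal tree node, multiplied down the
#' tree, so the parent/child mass structure the cascade assumes is real in
#' the data. The mixture profile is the proportion-weighted convex
#' combination of the archetypes plus truncated noise.
#'
#' @param archetypes Output of [simulate_archetypes()] (or the `archetypes`
#'   element of the other generators).
#' @param cfg A [simulation_config()].
#' @param proportions Optional matrix (samples x terminal classes) of fixed
#'   mixing proportions; rows must sum to 1. Default: hierarchical Dirichlet
#'   draws.
#' @return List with `betas` (beta matrix), `truth` (tibble `sample_id` plus
#'   one column per terminal class, rows summing to 1 exactly), `config`.
#' @export
simulate_mixtures <- function(archetypes, cfg = simulation_config(),
                              proportions = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  tree <- cfg$tree
  leaves <- tree$leaves
  miss <- setdiff(setdiff(leaves, "Tumor"), colnames(archetypes$archetypes))
  if (length(miss) > 0) {
    abort(paste0("archetypes missing classes: ", paste(miss, collapse = ", ")))
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed + 3L)

  n <- if (is.null(proportions)) cfg$n_mixtures else nrow(proportions)
  sample_ids <- sprintf("mix_%03d", seq_len(n))

  if (is.null(proportions)) {
    proportions <- t(vapply(seq_len(n), function(i) {
      mass <- c(TME = 1)
      for (p in unique(tree$edges$parent)) {
        ch <- hierarchy_children(tree, p)
        if (!(p %in% names(mass))) next
        if (length(ch) == 1) {
          mass[ch] <- mass[[p]]
        } else {
          alpha <- rep(cfg$concentration, length(ch))
          mass[ch] <- mass[[p]] * .rdirichlet1(alpha)
        }
      }
      out <- mass[leaves]
      out / sum(out)
    }, numeric(length(leaves))))
    colnames(proportions) <- leaves
  } else {
    proportions <- as.matrix(proportions)
    if (!identical(sort(colnames(proportions)), sort(leaves))) {
      abort("proportions columns must match the tree's terminal classes")
    }
    proportions <- proportions[, leaves, drop = FALSE]
    if (any(abs(rowSums(proportions) - 1) > 1e-8)) {
      abort("proportions rows must sum to 1")
    }
  }
  rownames(proportions) <- sample_ids

  A <- cbind(Tumor = archetypes$tumor_archetype,
             archetypes$archetypes[, setdiff(leaves, "Tumor"), drop = FALSE])
  A <- A[, leaves, drop = FALSE]
  betas <- vapply(seq_len(n), function(i) {
    .add_noise(drop(A %*% proportions[i, ]), cfg$noise_sd)
  }, numeric(nrow(A)))
  dimnames(betas) <- list(rownames(A), sample_ids)

  truth <- tibble::as_tibble(proportions, rownames = "sample_id")
  list(betas = beta_matrix(betas), truth = truth, config = cfg)
}

#' Simulate a complete study (panel + training data + mixtures)
#'
#' Convenience wrapper running [simulate_reference_panel()],
#' [simulate_tumor_normal()] and [simulate_mixtures()] on one shared
#' archetype set.
#'
#' @param cfg A [simulation_config()].
#' @return List with `panel`, `tumor`, `normal`, `differential_probes`,
#'   `training_purity`, `mixtures` (list `betas`, `truth`), `archetypes`,
#'   `config`.
#' @export
simulate_tme_study <- function(cfg = simulation_config()) {
  pan <- simulate_reference_panel(cfg)
  tn <- simulate_tumor_normal(cfg)
  mix <- simulate_mixtures(pan$archetypes, cfg)
  list(
    panel = pan$panel,
    tumor = tn$tumor,
    normal = tn$normal,
    differential_probes = tn$differential_probes,
    training_purity = tn$purity,
    mixtures = mix,
    archetypes = pan$archetypes,
    config = cfg
  )
}
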