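.GENE_CLASSES <- c("singleton", "WGD", "ySSD", "wSSD", "oSSD",
                   "WGD_SSD", "unannotated")

#' Simulation specification
#'
#' Parameters for the GTEx-like synthetic dataset. The defaults mirror the
#' study conditions of the real analysis: 13 named CNS regions with 97
#' samples each (within the cohort's 63-125 per-region range), the real
#' per-class gene counts (16,427 genes in total), per-class region-specific
#' fractions equal to the observed rates, families with 47% of size 2 and a
#' decaying tail, and class-specific baselines making young small-scale
#' duplicates the most weakly expressed class.
#'
#' Expression is log-normal on the RPKM scale: on log2 units, a gene's
#' value is baseline + region-specific elevation (planted genes only,
#' `log2(specificity_effect)` on the gene's target territory) + a shared
#' per-sample family factor (homogeneous families only) + covariate terms +
#' Gaussian noise, and RPKM = `2^value - 1` floored at 0. Region effects are
#' planted at the 7-territory level so the 13-to-7 merge never splits a
#' planted signal. The homogeneous-family factor varies by sample, not by
#' region, so co-expression structure leaves region labels exchangeable.
#'
#' @param samples_per_region Samples drawn in each of the 13 regions.
#' @param n_genes Named counts per class
#'   (`singleton`, `WGD`, `ySSD`, `wSSD`, `oSSD`, `WGD_SSD`, `unannotated`).
#' @param frac_region_specific Named per-class probabilities that a gene is
#'   planted region-specific.
#' @param specificity_effect Multiplicative fold elevation of the target
#'   territory mean on the RPKM scale (1 = no elevation).
#' @param baseline_mean_log2 Named per-class mean of the per-gene baseline
#'   (log2(RPKM + 1) units).
#' @param dispersion SD of per-gene baselines around the class mean.
#' @param baseline_floor_log2 Left-truncation of the baseline draw (log2
#'   units): the generator emulates the post-filter expressed-gene
#'   universe, which contains no genes silent in every region.
#' @param noise_sd Residual SD per observation (log2 units).
#' @param family_size_probs Probabilities of family sizes 2, 3, ... .
#' @param frac_homogeneous_families Probability a family is driven by one
#'   shared latent per-sample profile.
#' @param family_latent_sd SD of the shared family factor (log2 units).
#' @param frac_unexpressed_member Probability a family's total size exceeds
#'   its annotated membership by one (emulating members absent from the
#'   expression matrix).
#' @param covariate_effects List of linear coefficients on log2 abundance:
#'   `platform`, `age` (per year, centred), `sex`, `pc` (length 3).
#' @param covariate_gene_sd SD of the per-gene susceptibility multiplying
#'   the common covariate term (mean 1).
#' @param tandem_fraction Named per-class probability that a size-2 family
#'   is placed in tandem (< `tandem_bp` apart on one chromosome).
#' @param shared_region_prob Named per-class probability that a planted
#'   specific family member targets the family's region rather than an
#'   independent one (drives the pair-level shared-specificity gradient).
#' @param tandem_bp Tandem distance bound in base pairs.
#' @param rng_seed Integer seed.
#' @return A validated `sim_spec` list.
#' @export
sim_spec <- function(samples_per_region = 97L,
                     n_genes = c(singleton = 6092L, WGD = 5114L,
                                 ySSD = 1192L, wSSD = 1260L, oSSD = 1267L,
                                 WGD_SSD = 966L, unannotated = 536L),
                     frac_region_specific = c(singleton = 0.139,
                                              WGD = 0.157, ySSD = 0.286,
                                              wSSD = 0.240, oSSD = 0.156,
                                              WGD_SSD = 0.180,
                                              unannotated = 0.180),
                     specificity_effect = 4,
                     baseline_mean_log2 = c(singleton = 3.0, WGD = 3.2,
                                            ySSD = 1.8, wSSD = 2.8,
                                            oSSD = 3.0, WGD_SSD = 3.0,
                                            unannotated = 2.5),
                     dispersion = 0.75,
                     baseline_floor_log2 = 1.0,
                     noise_sd = 0.5,
                     family_size_probs = c(0.47, 0.22, 0.12, 0.08, 0.055,
                                           0.035, 0.02),
                     frac_homogeneous_families = 0.05,
                     family_latent_sd = 1.0,
                     frac_unexpressed_member = 0.15,
                     covariate_effects = list(platform = 0.3, age = 0.01,
                                              sex = 0.15,
                                              pc = c(0.2, 0.2, 0.2)),
                     covariate_gene_sd = 0.5,
                     tandem_fraction = c(WGD = 0.02, ySSD = 0.60,
                                         wSSD = 0.25, oSSD = 0.10,
                                         WGD_SSD = 0.10),
                     shared_region_prob = c(WGD = 0.31, ySSD = 0.59,
                                            wSSD = 0.50, oSSD = 0.50,
                                            WGD_SSD = 0.40),
                     tandem_bp = 1e6L,
                     rng_seed = 1L) {
  stopifnot(
    samples_per_region >= 1,
    all(.GENE_CLASSES %in% names(n_genes)),
    all(n_genes >= 0), sum(n_genes) > 0,
    all(.GENE_CLASSES %in% names(frac_region_specific)),
    all(frac_region_specific >= 0 & frac_region_specific <= 1),
    specificity_effect >= 1,
    all(.GENE_CLASSES %in% names(baseline_mean_log2)),
    dispersion >= 0, noise_sd >= 0,
    all(family_size_probs >= 0), sum(family_size_probs) > 0,
    frac_homogeneous_families >= 0, frac_homogeneous_families <= 1,
    family_latent_sd >= 0,
    frac_unexpressed_member >= 0, frac_unexpressed_member <= 1,
    all(tandem_fraction >= 0 & tandem_fraction <= 1),
    all(shared_region_prob >= 0 & shared_region_prob <= 1),
    tandem_bp > 0
  )
  structure(
    list(
      samples_per_region = as.integer(samples_per_region),
      n_genes = n_genes[.GENE_CLASSES],
      frac_region_specific = frac_region_specific[.GENE_CLASSES],
      specificity_effect = specificity_effect,
      baseline_mean_log2 = baseline_mean_log2[.GENE_CLASSES],
      dispersion = dispersion,
      baseline_floor_log2 = baseline_floor_log2,
      noise_sd = noise_sd,
      family_size_probs = family_size_probs / sum(family_size_probs),
      frac_homogeneous_families = frac_homogeneous_families,
      family_latent_sd = family_latent_sd,
      frac_unexpressed_member = frac_unexpressed_member,
      covariate_effects = covariate_effects,
      covariate_gene_sd = covariate_gene_sd,
      tandem_fraction = tandem_fraction,
      shared_region_prob = shared_region_prob,
      tandem_bp = as.integer(tandem_bp),
      rng_seed = as.integer(rng_seed)
    ),
    class = "sim_spec"
  )
}

# draw family sizes for a class until its paralogs are used up
.draw_family_sizes <- function(n_members, probs) {
  sizes <- integer(0)
  left <- n_members
  support <- seq_along(probs) + 1L
  while (left >= 2L) {
    s <- sample(support, 1L, prob = probs)
    s <- min(s, left)
    # never strand a lone member: fold a final leftover of 1 into this family
    if (left - s == 1L) s <- s + 1L
    sizes <- c(sizes, s)
    left <- left - s
  }
  sizes
}

#' Simulate a GTEx-like brain expression dataset with ground truth
#'
#' Generates an RPKM expression matrix over the 13 CNS regions, a sample
#' attribute table with covariates, a validated gene annotation (duplication
#' classes, families, phyletic ages, genomic coordinates with planted tandem
#' pairs) and the ground truth for every downstream classifier: per-gene
#' region-specificity flags and target territories, per-family homogeneity
#' and region-specificity, per-pair distance classes.
#'
#' @param spec A [sim_spec()].
#' @return A `sim_data` list: `expression` (`expr_matrix`, `raw_rpkm`),
#'   `samples`, `annotation`, and `truth` (list of tibbles `genes`,
#'   `families`, `pairs`).
#' @export
simulate_expression <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$rng_seed)
  ## ---- samples ----
  region_13 <- rep(.REGIONS_13, each = spec$samples_per_region)
  ns <- length(region_13)
  samples <- tibble::tibble(
    sample_id = sprintf("S%05d", seq_len(ns)),
    region_13 = region_13,
    region_7 = .to_region_7(region_13),
    platform = sample(c("HiSeq2000", "HiSeqX"), ns, replace = TRUE),
    age = round(runif(ns, 20, 70), 1),
    sex = sample(c("F", "M"), ns, replace = TRUE),
    pc1 = rnorm(ns), pc2 = rnorm(ns), pc3 = rnorm(ns)
  )

  ## ---- genes and classes ----
  class_of <- rep(.GENE_CLASSES, times = spec$n_genes)
  ng <- length(class_of)
  gene_id <- sprintf("G%05d", seq_len(ng))
  dup_category <- dplyr::case_when(
    class_of == "singleton" ~ "none",
    class_of %in% c("ySSD", "wSSD", "oSSD") ~ "SSD",
    class_of == "WGD" ~ "WGD",
    class_of == "WGD_SSD" ~ "WGD_SSD",
    TRUE ~ "unannotated"
  )
  ssd_age <- ifelse(class_of %in% c("ySSD", "wSSD", "oSSD"), class_of,
                    "not_applicable")
  status <- ifelse(class_of == "singleton", "singleton", "paralog")
  phyletic_age <- rep(NA_real_, ng)
  phyletic_age[class_of == "ySSD"] <- round(runif(sum(class_of == "ySSD"),
                                                  0.05, 0.25), 3)
  phyletic_age[class_of == "wSSD"] <- round(runif(sum(class_of == "wSSD"),
                                                  0.30, 0.50), 3)
  phyletic_age[class_of == "WGD"] <- round(runif(sum(class_of == "WGD"),
                                                 0.45, 0.60), 3)
  phyletic_age[class_of == "oSSD"] <- round(runif(sum(class_of == "oSSD"),
                                                  0.60, 0.95), 3)

  ## ---- families (within class, so pair categories match) ----
  family_id <- rep(NA_character_, ng)
  family_total_size <- rep(NA_integer_, ng)
  fam_counter <- 0L
  fam_rows <- list()
  for (cl in setdiff(.GENE_CLASSES, "singleton")) {
    members <- which(class_of == cl)
    if (length(members) < 2L) next
    members <- sample(members) # random family composition
    sizes <- .draw_family_sizes(length(members), spec$family_size_probs)
    pos <- 1L
    for (s in sizes) {
      fam_counter <- fam_counter + 1L
      fid <- sprintf("F%04d", fam_counter)
      idx <- members[pos:(pos + s - 1L)]
      pos <- pos + s
      extra <- stats::rbinom(1L, 1L, spec$frac_unexpressed_member)
      family_id[idx] <- fid
      family_total_size[idx] <- s + extra
      fam_rows[[fam_counter]] <- tibble::tibble(
        family_id = fid, class = cl, n_members = s,
        n_total = s + extra
      )
    }
  }
  families <- dplyr::bind_rows(fam_rows)
  families$is_homogeneous <-
    runif(nrow(families)) < spec$frac_homogeneous_families
  families$target_region <- sample(.REGIONS_7, nrow(families),
                                   replace = TRUE)

  ## ---- planted region specificity ----
  p_spec <- spec$frac_region_specific[class_of]
  is_specific <- runif(ng) < p_spec & spec$specificity_effect > 1
  target_region <- rep(NA_character_, ng)
  fam_of_gene <- match(family_id, families$family_id)
  share_p <- spec$shared_region_prob[class_of]
  share_p[is.na(share_p)] <- 0.5
  use_family_target <- !is.na(fam_of_gene) & runif(ng) < share_p
  target_region[is_specific & use_family_target] <-
    families$target_region[fam_of_gene[is_specific & use_family_target]]
  n_free <- sum(is_specific & !use_family_target)
  target_region[is_specific & !use_family_target] <-
    sample(.REGIONS_7, n_free, replace = TRUE)

  ## ---- genomic coordinates with planted tandem pairs ----
  chroms <- paste0("chr", 1:22)
  chrom <- sample(chroms, ng, replace = TRUE)
  start <- round(runif(ng, 1, 2.4e8))
  pair_truth <- list()
  pair_families <- families[families$n_members == 2L, ]
  for (i in seq_len(nrow(pair_families))) {
    idx <- which(family_id == pair_families$family_id[i])
    cl <- pair_families$class[i]
    p_tandem <- spec$tandem_fraction[cl]
    if (is.na(p_tandem)) p_tandem <- 0
    cls <- if (runif(1) < p_tandem) "tandem"
           else if (runif(1) < 0.85) "inter_chromosomal"
           else "intra_chromosomal"
    if (cls == "tandem") {
      chrom[idx[2]] <- chrom[idx[1]]
      start[idx[2]] <- start[idx[1]] +
        sample(c(-1, 1), 1) * round(runif(1, 1e3, spec$tandem_bp - 1))
    } else if (cls == "inter_chromosomal") {
      chrom[idx[2]] <- sample(setdiff(chroms, chrom[idx[1]]), 1)
    } else {
      chrom[idx[2]] <- chrom[idx[1]]
      start[idx[2]] <- start[idx[1]] +
        sample(c(-1, 1), 1) * round(runif(1, spec$tandem_bp, 5e7))
    }
    pair_truth[[length(pair_truth) + 1L]] <- tibble::tibble(
      gene_a = min(gene_id[idx]), gene_b = max(gene_id[idx]),
      dup_category = dup_category[idx[1]], distance_class = cls
    )
  }
  start <- pmax(start, 1)

  ## ---- expression ----
  # left-truncated log-normal abundance model: the generator emulates the
  # post-filter expressed-gene universe, which contains no genes that are
  # essentially silent in every region
  baseline <- pmax(rnorm(ng, spec$baseline_mean_log2[class_of],
                         spec$dispersion), spec$baseline_floor_log2)
  mu <- matrix(baseline, ng, ns)
  # planted specificity: elevate the target territory
  effect_log2 <- log2(spec$specificity_effect)
  if (any(is_specific)) {
    r7 <- samples$region_7
    for (g in which(is_specific)) {
      mu[g, r7 == target_region[g]] <- mu[g, r7 == target_region[g]] +
        effect_log2
    }
  }
  # homogeneous families: one shared per-sample latent factor
  hom_fams <- families$family_id[families$is_homogeneous]
  for (fid in hom_fams) {
    z <- rnorm(ns, 0, spec$family_latent_sd)
    idx <- which(family_id == fid)
    mu[idx, ] <- mu[idx, ] + rep(z, each = length(idx))
  }
  # covariates: common per-sample term, per-gene susceptibility
  ce <- spec$covariate_effects
  covar_term <- ce$platform * (samples$platform == "HiSeqX") +
    ce$age * (samples$age - 45) +
    ce$sex * (samples$sex == "M") +
    ce$pc[1] * samples$pc1 + ce$pc[2] * samples$pc2 + ce$pc[3] * samples$pc3
  gene_susc <- rnorm(ng, 1, spec$covariate_gene_sd)
  mu <- mu + outer(gene_susc, covar_term)
  mu <- mu + matrix(rnorm(ng * ns, 0, spec$noise_sd), ng, ns)
  rpkm <- pmax(2^mu - 1, 0)
  dimnames(rpkm) <- list(gene_id, samples$sample_id)

  annotation <- validate_annotation(tibble::tibble(
    gene_id = gene_id, status = status, dup_category = dup_category,
    ssd_age = ssd_age, family_id = family_id,
    family_total_size = family_total_size, phyletic_age = phyletic_age,
    chrom = chrom, start = start, class = class_of
  ))

  truth_genes <- tibble::tibble(
    gene_id = gene_id, class = class_of,
    is_region_specific = is_specific,
    target_region = target_region
  )
  truth_families <- families |>
    dplyr::select("family_id", "class", "n_members", "n_total",
                  "is_homogeneous", "target_region")
  truth_pairs <- dplyr::bind_rows(pair_truth)

  structure(
    list(
      expression = expr_matrix(rpkm, "raw_rpkm"),
      samples = samples,
      annotation = annotation,
      truth = list(genes = truth_genes, families = truth_families,
                   pairs = truth_pairs)
    ),
    class = "sim_data"
  )
}

#' @export
print.sim_data <- function(x, ...) {
  cat(sprintf("<sim_data> %d genes x %d samples; %d families; %d planted specific genes\n",
              nrow(x$expression), ncol(x$expression),
              nrow(x$truth$families),
              sum(x$truth$genes$is_region_specific)))
  invisible(x)
}

#' Small fixed simulated dataset
#'
#' A ~600-gene, 13 x 10-sample dataset with all seven annotation classes,
#' tens of families (several homogeneous) and planted tandem ySSD pairs,
#' reproducible from the seed. Intended for examples and fast end-to-end
#' runs.
#'
#' @param seed Integer seed.
#' @return A `sim_data` list (see [simulate_expression()]).
#' @export
fixture_small <- function(seed = 1L) {
  simulate_expression(sim_spec(
    samples_per_region = 10L,
    n_genes = c(singleton = 200L, WGD = 140L, ySSD = 120L, wSSD = 50L,
                oSSD = 50L, WGD_SSD = 25L, unannotated = 15L),
    frac_homogeneous_families = 0.25,
    rng_seed = as.integer(seed)
  ))
}
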