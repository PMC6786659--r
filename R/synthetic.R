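# Fully seeded synthetic-data generator.  Emulates the statistical structure
# the method exploits: planted driver genes carry elevated
# class-characteristic mutation signals (loss-of-function categories for
# TSG-like drivers, damaging and positionally clustered missense for OG-like
# drivers), drivers are preferentially interconnected in a scale-free PPI
# network, and in the multi-disease setting descriptor similarity correlates
# with driver-set overlap.

#' Synthetic-data configuration
#'
#' Defaults describe the standard benchmark world: a modest desk-scale
#' cohort with clearly mutated drivers (`driver_effect = 8`) and a driver
#' interaction module (`module_boost = 0.3`) on top of a preferential
#' attachment network.  Setting `driver_effect = 1` and `module_boost = 0`
#' removes all signal (null world).
#'
#' @param n_genes Number of genes in the universe.
#' @param n_samples Number of tumor samples.
#' @param n_drivers Planted drivers per class (OG and TSG) in the
#'   single-disease setting.
#' @param driver_effect Median multiplier on driver-characteristic mutation
#'   category rates (1 = no signal).
#' @param penetrance_sd Spread of per-driver effect exponents: driver `g`
#'   gets multiplier `driver_effect^(u_g)` with
#'   `u_g ~ N(1, penetrance_sd)` truncated at 0, so some drivers are
#'   heavily mutated and others nearly silent (as observed for real
#'   drivers).  With `driver_effect = 1` every multiplier is exactly 1
#'   regardless of this value.
#' @param background_rate Per-gene per-sample mutation probability.
#' @param gene_length_dispersion SD of the log-normal gene-level rate
#'   multiplier standing in for gene length / background heterogeneity.
#' @param ppi_m Edges added per node in the preferential-attachment network.
#' @param module_boost Extra edge probability between participating driver
#'   pairs (0 = no module).
#' @param module_participation Probability that a driver takes part in the
#'   interaction module.  Drivers are *more likely* to sit in protein
#'   complexes than other genes, not guaranteed to; non-participating
#'   drivers carry no network signal and can only be found through their
#'   mutations.
#' @param n_diseases Number of diseases (1 = pan-cancer).
#' @param drivers_per_disease Drivers per class per disease when
#'   `n_diseases > 1`.
#' @param shared_fraction Fraction of each disease's drivers shared by all
#'   diseases.
#' @param seed RNG seed; the whole generation is a deterministic function of
#'   the configuration.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_genes = 400, n_samples = 150, n_drivers = 20,
                         driver_effect = 8, penetrance_sd = 0.5,
                         background_rate = 0.02,
                         gene_length_dispersion = 0.5, ppi_m = 2,
                         module_boost = 0.3, module_participation = 0.7,
                         n_diseases = 1,
                         drivers_per_disease = 6, shared_fraction = 0.5,
                         seed = 1) {
  stopifnot(n_genes > 0, n_samples > 0, n_drivers > 0, n_drivers < n_genes,
            driver_effect >= 1, penetrance_sd >= 0,
            background_rate > 0, background_rate < 1,
            gene_length_dispersion >= 0, ppi_m >= 1,
            module_boost >= 0, module_boost <= 1,
            module_participation >= 0, module_participation <= 1,
            n_diseases >= 1, shared_fraction >= 0, shared_fraction <= 1)
  if (n_diseases > 1 && drivers_per_disease < 2) {
    stop("drivers_per_disease must be at least 2 in the multi-disease setting")
  }
  structure(as.list(environment()), class = "synth_config")
}

# Baseline mutation category mix (fractions of all somatic mutations).
.category_mix <- c(missense = 0.50, silent = 0.22, nonsense = 0.08,
                   frameshift = 0.08, splice_site = 0.06, other = 0.06)

# Driver-set structure for the multi-disease world.  Diseases are organized
# in pairs: every disease has `n_shared` globally shared drivers; within a
# pair, most specific drivers are common to both members and one is unique.
# This gives driver-set Jaccard overlap that is high within a pair and low
# across pairs -- the structure the descriptor kernel is built to mirror.
.disease_driver_sets <- function(pool, cfg) {
  n_shared <- round(cfg$shared_fraction * cfg$drivers_per_disease)
  n_specific <- cfg$drivers_per_disease - n_shared
  n_pair_common <- if (n_specific > 1) n_specific - 1 else 0
  n_unique <- n_specific - n_pair_common
  n_pairs <- ceiling(cfg$n_diseases / 2)
  need <- n_shared + n_pairs * n_pair_common + cfg$n_diseases * n_unique
  if (need > length(pool)) stop("driver pool too small for the disease structure")
  take <- function(n) {
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  shared <- take(n_shared)
  pair_common <- lapply(seq_len(n_pairs), function(p) take(n_pair_common))
  sets <- lapply(seq_len(cfg$n_diseases), function(i) {
    p <- ceiling(i / 2)
    c(shared, pair_common[[p]], take(n_unique))
  })
  names(sets) <- sprintf("D%02d", seq_len(cfg$n_diseases))
  sets
}

# Descriptors mirroring the pair structure: all synthetic diseases are
# carcinomas (one common type bit, as for most real cancer types), each
# disease pair shares one localization bit, and each disease adds one unique
# localization bit.  Descriptor inner products are then 3 on the diagonal,
# 2 within a pair and 1 across pairs, tracking driver-set overlap.
.disease_descriptors <- function(n_diseases) {
  vocab <- disease_vocabulary()
  n_pairs <- ceiling(n_diseases / 2)
  if (n_pairs + n_diseases > length(vocab$localizations)) {
    stop("too many synthetic diseases for the descriptor vocabulary")
  }
  psi <- t(vapply(seq_len(n_diseases), function(i) {
    p <- ceiling(i / 2)
    build_descriptor(types = "carcinoma",
                     localizations = vocab$localizations[c(p, n_pairs + i)])
  }, integer(43)))
  rownames(psi) <- sprintf("D%02d", seq_len(n_diseases))
  storage.mode(psi) <- "numeric"
  psi
}

#' Generate a synthetic benchmark dataset
#'
#' Per-gene per-category mutation counts are Poisson with a log-normal
#' gene-level multiplier; TSG-like drivers have their nonsense, frameshift
#' and splice-site rates multiplied by `driver_effect`, OG-like drivers gain
#' extra damaging missense mutations (PolyPhen2 in (0.6, 1)) concentrated on
#' three positional hotspots.  The PPI network is preferential attachment
#' plus extra edges among drivers.  In the multi-disease setting the
#' elevated rates apply only within the samples of the diseases a gene
#' drives.  Byte-identical output for identical configurations.
#'
#' @param cfg A [synth_config()].
#' @return List with elements `table` ([mutation_table()]), `net`
#'   ([ppi_network()]), `truth` (list with per-class pan-cancer driver sets
#'   and, when `n_diseases > 1`, per-disease sets), and `descriptors`
#'   (matrix or `NULL`), plus a `pairs` data frame of (gene, disease) truth
#'   associations per class.
#' @export
synth_generate <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    genes <- sprintf("G%04d", seq_len(cfg$n_genes))
    samples <- sprintf("S%04d", seq_len(cfg$n_samples))
    diseases <- if (cfg$n_diseases == 1) "PAN"
                else sprintf("D%02d", seq_len(cfg$n_diseases))
    sample_disease <- rep(diseases, length.out = cfg$n_samples)

    # planted drivers (disjoint pools per class)
    pool <- sample(genes)
    if (cfg$n_diseases == 1) {
      og_sets <- list(PAN = pool[seq_len(cfg$n_drivers)])
      tsg_sets <- list(PAN = pool[cfg$n_drivers + seq_len(cfg$n_drivers)])
    } else {
      half <- floor(length(pool) / 2)
      og_sets <- .disease_driver_sets(pool[seq_len(half)], cfg)
      tsg_sets <- .disease_driver_sets(pool[half + seq_len(half)], cfg)
    }
    og_all <- sort(unique(unlist(og_sets)))
    tsg_all <- sort(unique(unlist(tsg_sets)))

    # gene-level rate multipliers and protein lengths
    mult <- exp(stats::rnorm(cfg$n_genes, 0, cfg$gene_length_dispersion))
    lens <- pmax(50L, round(300 * mult))
    # per-driver effect multipliers: driver_effect^u, u ~ N(1, penetrance_sd)
    all_driver_genes <- sort(unique(c(unlist(og_sets), unlist(tsg_sets))))
    u <- pmax(0, stats::rnorm(length(all_driver_genes), 1, cfg$penetrance_sd))
    driver_mult <- stats::setNames(cfg$driver_effect^u, all_driver_genes)
    hotspots <- lapply(seq_len(cfg$n_genes),
                       function(i) sample.int(lens[i], 3, replace = TRUE))
    names(mult) <- names(lens) <- names(hotspots) <- genes

    tsg_cats <- c("nonsense", "frameshift", "splice_site")
    recs <- list()
    for (d in diseases) {
      d_samples <- samples[sample_disease == d]
      lam0 <- length(d_samples) * cfg$background_rate * mult
      og_d <- og_sets[[d]]; tsg_d <- tsg_sets[[d]]
      for (categ in names(.category_mix)) {
        lam <- lam0 * .category_mix[[categ]]
        if (categ %in% tsg_cats) {
          lam[tsg_d] <- lam[tsg_d] * driver_mult[tsg_d]
        }
        counts <- stats::rpois(cfg$n_genes, lam)
        idx <- rep.int(seq_len(cfg$n_genes), counts)
        if (length(idx) > 0) {
          n <- length(idx)
          pos <- floor(stats::runif(n) * lens[idx]) + 1
          pp <- if (categ == "missense") stats::runif(n) else rep(NA_real_, n)
          recs[[length(recs) + 1]] <- data.frame(
            gene = genes[idx],
            sample = sample(d_samples, n, replace = TRUE),
            disease = d, category = categ,
            protein_position = pos,
            polyphen2 = pp, stringsAsFactors = FALSE)
        }
      }
      # extra damaging, hotspot-clustered missense on OG drivers
      if (cfg$driver_effect > 1 && length(og_d) > 0) {
        lam_extra <- lam0[og_d] * .category_mix[["missense"]] *
          (driver_mult[og_d] - 1)
        counts <- stats::rpois(length(og_d), lam_extra)
        idx <- rep.int(seq_along(og_d), counts)
        if (length(idx) > 0) {
          n <- length(idx)
          g <- og_d[idx]
          pos <- vapply(g, function(gg) sample(hotspots[[gg]], 1), numeric(1))
          recs[[length(recs) + 1]] <- data.frame(
            gene = g,
            sample = sample(d_samples, n, replace = TRUE),
            disease = d, category = "missense",
            protein_position = unname(pos),
            polyphen2 = stats::runif(n, 0.6, 1), stringsAsFactors = FALSE)
        }
      }
    }
    records <- if (length(recs) > 0) do.call(rbind, recs) else
      data.frame(gene = character(0), sample = character(0),
                 disease = character(0), category = character(0),
                 protein_position = numeric(0), polyphen2 = numeric(0),
                 stringsAsFactors = FALSE)
    table <- mutation_table(records, universe = genes)

    # scale-free PPI plus a driver module
    g <- igraph::sample_pa(cfg$n_genes, power = 1, m = cfg$ppi_m,
                           directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    vertex_gene <- sample(genes)  # random vertex -> gene assignment
    edges <- cbind(vertex_gene[el[, 1]], vertex_gene[el[, 2]])
    # Interaction modules: drivers interconnect within pathway modules.  In
    # the multi-disease setting each disease pair-group has its own module
    # (related cancers share driver mechanisms); globally shared drivers
    # belong to every group and bridge the modules.  Only a fraction of
    # drivers (module_participation) takes part at all.
    drivers <- sort(unique(c(og_all, tsg_all)))
    participating <- drivers[stats::runif(length(drivers)) <
                               cfg$module_participation]
    groups <- if (cfg$n_diseases == 1) list(participating) else {
      lapply(seq_len(ceiling(cfg$n_diseases / 2)), function(p) {
        ds <- intersect(c(2 * p - 1, 2 * p), seq_len(cfg$n_diseases))
        intersect(sort(unique(c(unlist(og_sets[ds]), unlist(tsg_sets[ds])))),
                  participating)
      })
    }
    if (cfg$module_boost > 0) {
      for (members in groups) {
        if (length(members) < 2) next
        dp <- t(utils::combn(members, 2))
        add <- stats::runif(nrow(dp)) < cfg$module_boost
        edges <- rbind(edges, dp[add, , drop = FALSE])
      }
    }
    net <- suppressWarnings(ppi_network(edges, nodes = genes))

    descriptors <- if (cfg$n_diseases > 1)
      .disease_descriptors(cfg$n_diseases) else NULL
    mk_pairs <- function(sets) {
      do.call(rbind, lapply(names(sets), function(d) {
        data.frame(gene = sets[[d]], disease = d, stringsAsFactors = FALSE)
      }))
    }
    list(table = table, net = net,
         truth = list(og = og_sets, tsg = tsg_sets,
                      og_all = og_all, tsg_all = tsg_all),
         pairs = list(og = mk_pairs(og_sets), tsg = mk_pairs(tsg_sets)),
         descriptors = descriptors)
  })
}

#' Count recovered planted drivers among the top of a ranking
#'
#' @param truth_genes Character vector of planted driver genes.
#' @param ranking A [ranked_genes()] data frame.
#' @param top_k Integer vector of list depths.
#' @return Data frame (top_k, recovered).
#' @export
truth_report <- function(truth_genes, ranking, top_k) {
  recovered <- vapply(top_k, function(k) {
    sum(utils::head(ranking$gene, k) %in% truth_genes)
  }, numeric(1))
  data.frame(top_k = top_k, recovered = recovered)
}
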