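#' Simulation parameters
#'
#' Parameters of the synthetic whole-transcriptome generator. The defaults
#' mirror the study design this pipeline targets: two growth-rate groups of
#' four animals each, three RNA classes (200 mRNAs, 50 miRNAs, 100
#' lncRNAs), negative-binomial counts, a planted fraction of two-fold
#' differential features per class, and 20 planted sponge triples.
#'
#' Each planted triple is driven by a per-sample latent miRNA activity
#' `a_s = lfc_de * g_s + sponge_strength * e_s`, with `g_s = +1/2` in the
#' high group, `-1/2` in the low group and `e_s ~ N(0, 1)` shared by all
#' members of the triple. The triple's miRNA log2 mean shifts by `+a_s`,
#' its lncRNA and mRNA partners by `-a_s` (orientation randomly flipped per
#' triple), so every planted member has a group-mean log2 ratio of exactly
#' `±lfc_de` and the within-group wobble `sponge_strength * e_s` is what
#' makes the miRNA-partner Spearman correlation strongly negative and the
#' lncRNA-mRNA correlation strongly positive even at n = 4 per group.
#' `mirnas_per_triple` miRNAs (default 2) share each planted lncRNA-mRNA
#' pair so that the shared-miRNA hypergeometric test has an overlap to
#' detect.
#'
#' @param n_per_group Samples per group. Default 4.
#' @param n_mrna,n_mirna,n_lncrna Features per RNA class.
#' @param frac_de Named fractions of planted (non-triple) differential
#'   features per class.
#' @param lfc_de Planted log2 effect size. Default 2.
#' @param nb_dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`). Default 0.05.
#' @param base_log_mean,base_log_sd Log-normal baseline mean parameters for
#'   background mRNA/lncRNA features.
#' @param mirna_base_log_mean,mirna_base_log_sd Baseline parameters for
#'   background miRNAs. Mature-miRNA libraries are dominated by a few very
#'   abundant constitutive species, so the background sits much higher than
#'   the planted features; this also keeps per-million normalization stable
#'   when planted miRNAs shift between groups.
#' @param triple_log_mean,triple_log_sd Baseline parameters for planted
#'   triple members (moderately high expression, so count noise does not
#'   swamp the rank signal).
#' @param n_triples Planted sponge triples. Default 20.
#' @param mirnas_per_triple Shared miRNAs per planted triple. Default 2.
#' @param sponge_strength SD (log2 units) of the shared within-group latent
#'   activity. Default 1.
#' @param n_decoy_edges Random decoy edges added to the target map.
#'   Default 200.
#' @param seed Integer seed.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_per_group = 4L, n_mrna = 200L, n_mirna = 50L,
                       n_lncrna = 100L,
                       frac_de = c(mRNA = 0.1, miRNA = 0.1, lncRNA = 0.1),
                       lfc_de = 2, nb_dispersion = 0.05,
                       base_log_mean = log(200), base_log_sd = 1.2,
                       mirna_base_log_mean = log(5000), mirna_base_log_sd = 1.5,
                       triple_log_mean = log(500), triple_log_sd = 0.5,
                       n_triples = 20L, mirnas_per_triple = 2L,
                       sponge_strength = 1, n_decoy_edges = 200L,
                       seed = 1L) {
  p <- list(n_per_group = as.integer(n_per_group), n_mrna = as.integer(n_mrna),
            n_mirna = as.integer(n_mirna), n_lncrna = as.integer(n_lncrna),
            frac_de = frac_de, lfc_de = lfc_de,
            nb_dispersion = nb_dispersion,
            base_log_mean = base_log_mean, base_log_sd = base_log_sd,
            mirna_base_log_mean = mirna_base_log_mean,
            mirna_base_log_sd = mirna_base_log_sd,
            triple_log_mean = triple_log_mean, triple_log_sd = triple_log_sd,
            n_triples = as.integer(n_triples),
            mirnas_per_triple = as.integer(mirnas_per_triple),
            sponge_strength = sponge_strength,
            n_decoy_edges = as.integer(n_decoy_edges), seed = as.integer(seed))
  class(p) <- "sim_params"
  validate_sim_params(p)
}

validate_sim_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  if (p$n_per_group < 2) abort("n_per_group must be >= 2")
  if (any(p$frac_de < 0) || any(p$frac_de > 1)) abort("frac_de must be in [0, 1]")
  if (!all(RNA_CLASSES %in% names(p$frac_de))) {
    abort("frac_de must be named for mRNA, miRNA, lncRNA")
  }
  if (p$nb_dispersion <= 0) abort("nb_dispersion must be positive")
  n_triple_mirnas <- p$n_triples * p$mirnas_per_triple
  if (p$n_triples > min(p$n_mrna, p$n_lncrna) || n_triple_mirnas > p$n_mirna) {
    abort("n_triples too large for the feature counts")
  }
  p
}

sim_ids <- function(p) {
  list(mRNA = sprintf("mRNA_%04d", seq_len(p$n_mrna)),
       miRNA = sprintf("miR_%03d", seq_len(p$n_mirna)),
       lncRNA = sprintf("lnc_%04d", seq_len(p$n_lncrna)))
}

#' Simulate a whole-transcriptome dataset with planted ground truth
#'
#' Draws negative-binomial count matrices for the three RNA classes over a
#' two-group design, plants two-fold differential features and sponge
#' triples (see [sim_params()]), builds the corresponding miRNA-target map
#' (true edges from every planted triple plus uniformly random decoy
#' edges), and returns the ground truth needed to score any downstream
#' stage. Fully reproducible from `params$seed`.
#'
#' @param params A [sim_params()] list.
#' @return A list:
#' * `counts`: named list of wide count tibbles (`mRNA`, `miRNA`, `lncRNA`);
#' * `samples`: the sample sheet;
#' * `target_map`: predicted-interaction tibble;
#' * `truth`: list with `de_features` (tibble `feature_id`, `rna_class`,
#'   `direction`), `triples` (tibble `lncrna_id`, `mirna_id`, `mrna_id`),
#'   and `pairs` (distinct planted `lncrna_id`/`mrna_id` pairs).
#' @export
simulate_dataset <- function(params = sim_params()) {
  p <- validate_sim_params(params)
  set.seed(p$seed)
  n_s <- 2L * p$n_per_group
  samples <- tibble(sample_id = sprintf("S%02d", seq_len(n_s)),
                    group = factor(rep(c("high", "low"), each = p$n_per_group),
                                   levels = c("high", "low")))
  g <- if_else(samples$group == "high", 0.5, -0.5)
  ids <- sim_ids(p)
  n_feat <- c(mRNA = p$n_mrna, miRNA = p$n_mirna, lncRNA = p$n_lncrna)

  # planted triple membership: first features of each class, disjoint
  tri <- tibble(
    lncrna_id = ids$lncRNA[seq_len(p$n_triples)],
    mrna_id = ids$mRNA[seq_len(p$n_triples)])
  tri_mirnas <- split(ids$miRNA[seq_len(p$n_triples * p$mirnas_per_triple)],
                      rep(seq_len(p$n_triples), each = p$mirnas_per_triple))

  # per-class log2 mean matrices
  log2mu <- lapply(RNA_CLASSES, function(cl) {
    base <- if (cl == "miRNA") {
      exp(rnorm(n_feat[[cl]], p$mirna_base_log_mean, p$mirna_base_log_sd))
    } else {
      exp(rnorm(n_feat[[cl]], p$base_log_mean, p$base_log_sd))
    }
    matrix(rep(log2(base), n_s), ncol = n_s,
           dimnames = list(ids[[cl]], samples$sample_id))
  })
  names(log2mu) <- RNA_CLASSES

  de_truth <- tibble(feature_id = character(), rna_class = character(),
                     direction = character())

  # sponge triples: shared latent activity per triple
  if (p$n_triples > 0) {
    for (t in seq_len(p$n_triples)) {
      a <- p$lfc_de * g + p$sponge_strength * rnorm(n_s)
      orient <- sample(c(1, -1), 1)
      a <- a * orient
      members <- list(
        list(cl = "miRNA", id = tri_mirnas[[t]], sign = +1),
        list(cl = "lncRNA", id = tri$lncrna_id[t], sign = -1),
        list(cl = "mRNA", id = tri$mrna_id[t], sign = -1))
      for (mb in members) {
        base <- log2(exp(rnorm(length(mb$id), p$triple_log_mean, p$triple_log_sd)))
        log2mu[[mb$cl]][mb$id, ] <- rep(base, n_s) +
          rep(mb$sign * a, each = length(mb$id))
        dirn <- if (mb$sign * orient > 0) "up" else "down"
        de_truth <- bind_rows(de_truth,
                              tibble(feature_id = mb$id, rna_class = mb$cl,
                                     direction = dirn))
      }
    }
  }

  # plain planted DE features among the remaining ones
  for (cl in RNA_CLASSES) {
    free <- setdiff(ids[[cl]], de_truth$feature_id)
    n_de <- round(p$frac_de[[cl]] * n_feat[[cl]])
    n_de <- min(n_de, length(free))
    if (n_de > 0) {
      chosen <- sample(free, n_de)
      dirs <- rep(c("up", "down"), length.out = n_de)
      shift <- if_else(dirs == "up", p$lfc_de, -p$lfc_de)
      log2mu[[cl]][chosen, ] <- log2mu[[cl]][chosen, , drop = FALSE] +
        outer(shift, g)
      de_truth <- bind_rows(de_truth, tibble(feature_id = chosen,
                                             rna_class = cl, direction = dirs))
    }
  }

  counts <- lapply(RNA_CLASSES, function(cl) {
    mu <- 2^log2mu[[cl]]
    m <- matrix(rnbinom(length(mu), mu = mu, size = 1 / p$nb_dispersion),
                nrow = nrow(mu), dimnames = dimnames(mu))
    matrix_to_counts(m, cl)
  })
  names(counts) <- RNA_CLASSES

  # target map: true triple edges + uniform decoys
  true_edges <- if (p$n_triples > 0) {
    purrr::map_dfr(seq_len(p$n_triples), function(t) {
      mi <- tri_mirnas[[t]]
      bind_rows(tibble(mirna_id = mi, target_id = tri$lncrna_id[t],
                       target_class = "lncRNA"),
                tibble(mirna_id = mi, target_id = tri$mrna_id[t],
                       target_class = "mRNA"))
    })
  } else {
    tibble(mirna_id = character(), target_id = character(),
           target_class = character())
  }
  decoys <- tibble(
    mirna_id = sample(ids$miRNA, p$n_decoy_edges, replace = TRUE),
    target_class = sample(c("mRNA", "lncRNA"), p$n_decoy_edges, replace = TRUE))
  decoys$target_id <- if_else(decoys$target_class == "mRNA",
                              sample(ids$mRNA, p$n_decoy_edges, replace = TRUE),
                              sample(ids$lncRNA, p$n_decoy_edges, replace = TRUE))
  target_map <- distinct(bind_rows(true_edges,
                                   decoys[c("mirna_id", "target_id",
                                            "target_class")]))

  triples <- if (p$n_triples > 0) {
    purrr::map_dfr(seq_len(p$n_triples), function(t) {
      tibble(lncrna_id = tri$lncrna_id[t], mirna_id = tri_mirnas[[t]],
             mrna_id = tri$mrna_id[t])
    })
  } else {
    tibble(lncrna_id = character(), mirna_id = character(),
           mrna_id = character())
  }

  list(counts = counts, samples = samples, target_map = target_map,
       truth = list(de_features = de_truth,
                    triples = triples,
                    pairs = distinct(triples[c("lncrna_id", "mrna_id")])))
}

#' Simulate per-animal phenotype records
#'
#' Draws normal per-animal values for each (trait, group) at the given
#' means and SDs — the raw-data counterpart of a published
#' mean ± SD table, used to exercise the raw-data group statistics.
#'
#' @param traits Data frame with columns `trait`, `group`, `mean`, `sd`.
#' @param n_per_group Animals per group. Default 4.
#' @param seed Integer seed.
#' @return Long tibble: `trait`, `group`, `animal`, `value`.
#' @export
simulate_phenotypes <- function(traits, n_per_group = 4L, seed = 1L) {
  need <- c("trait", "group", "mean", "sd")
  if (!all(need %in% names(traits))) {
    abort(sprintf("traits needs columns: %s", paste(need, collapse = ", ")))
  }
  set.seed(as.integer(seed))
  traits |>
    as_tibble() |>
    dplyr::rowwise() |>
    dplyr::reframe(trait = .data$trait, group = .data$group,
                   animal = sprintf("%s_%02d", .data$group,
                                    seq_len(n_per_group)),
                   value = rnorm(n_per_group, .data$mean, .data$sd))
}

#' Simulate a qPCR Ct table from planted ground truth
#'
#' Generates cycle thresholds under the standard inverse-log2 model
#' `Ct = baseline - log2(relative expression) + noise` for a set of planted
#' differential genes plus a flat reference gene, so that the 2^-ddCt
#' analysis should recover fold-changes of `2^lfc_de` up to noise.
#'
#' @param truth Truth list from [simulate_dataset()] (its `de_features` are
#'   eligible targets), or a tibble with `feature_id` and `direction`.
#' @param samples Sample sheet.
#' @param genes Gene ids to assay; default the first 3 DE features.
#' @param lfc_de Planted log2 effect (must match the generator's).
#' @param reference Reference gene id added to the table. Default `"GAPDH"`.
#' @param baseline_ct Mean target Ct at baseline expression. Default 28.
#' @param reference_ct Mean reference Ct. Default 18.
#' @param noise_sd Per-well Ct noise SD. Default 0.15.
#' @param n_replicates Technical replicates per well. Default 3.
#' @param seed Integer seed.
#' @return A long Ct tibble (`sample_id`, `gene_id`, `replicate`, `ct`).
#' @export
simulate_qpcr <- function(truth, samples, genes = NULL, lfc_de = 2,
                          reference = "GAPDH", baseline_ct = 28,
                          reference_ct = 18, noise_sd = 0.15,
                          n_replicates = 3L, seed = 1L) {
  de <- if (is.data.frame(truth)) truth else truth$de_features
  if (is.null(genes)) genes <- head(de$feature_id, 3)
  stopifnot(all(genes %in% de$feature_id))
  samples <- validate_sample_sheet(samples)
  set.seed(as.integer(seed))
  g <- if_else(samples$group == "high", 0.5, -0.5)
  dir_of <- setNames(if_else(de$direction == "up", 1, -1), de$feature_id)

  rows <- purrr::map_dfr(c(genes, reference), function(gene) {
    log2expr <- if (gene == reference) rep(0, nrow(samples)) else
      dir_of[gene] * lfc_de * g
    base <- if (gene == reference) reference_ct else baseline_ct
    purrr::map_dfr(seq_len(n_replicates), function(r) {
      tibble(sample_id = samples$sample_id, gene_id = gene,
             replicate = r,
             ct = base - log2expr + rnorm(nrow(samples), 0, noise_sd))
    })
  })
  arrange(rows, .data$sample_id, .data$gene_id, .data$replicate)
}
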