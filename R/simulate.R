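#' Configuration for the synthetic corpus generator
#'
#' Defines the study conditions of a self-contained synthetic corpus with a
#' planted compound -> target-gene -> pathway linkage expressed in both the
#' fingerprints and the signatures, so every pipeline stage is testable
#' without external downloads.
#'
#' The generative model: every target gene carries (a) a latent signature
#' template -- a `sig_dim`-vector of independent standard-normal entries --
#' and (b) a private structural motif of `motif_bits_per_target` reserved
#' fingerprint bit positions.  A compound targeting gene `g` gets the
#' motif bits of `g` plus background bits at `base_bit_rate`, each bit then
#' flipped independently with probability `structure_noise_rate`; its
#' replicate signatures are the template plus Gaussian noise
#' (`signature_noise_sd`).  Genetic-perturbation columns for `g` are the
#' same template plus independent noise per replicate and perturbation
#' type.  Pathways partition the target genes; the truth maps each compound
#' to every pathway containing its target.  Decoy compounds get random
#' fingerprints, pure-noise signatures and an empty truth.
#'
#' Target genes are the first `n_genes` identifiers of the signature's own
#' gene universe, so direct-signature enrichment has a well-defined overlap
#' with the pathways (as for L1000 landmark genes that are themselves
#' perturbed).
#'
#' @param n_compounds number of compounds including decoys (default 200).
#' @param n_genes number of perturbed (target) genes (default 30).
#' @param n_pathways number of pathway gene sets (default 6).
#' @param genes_per_pathway pathway size (default 5); pathways are disjoint
#'   and `n_pathways * genes_per_pathway` must not exceed `n_genes`.
#' @param n_bits fingerprint length (default 2048).
#' @param sig_dim signature dimension (default 978, the landmark-gene
#'   convention).
#' @param replicates_per_gene GP replicates per gene and perturbation type
#'   (default 1).
#' @param pert_types perturbation types to simulate (default all three, so
#'   each gene has 3 GP columns by default).
#' @param n_sig_per_compound replicate signatures per compound (default 3).
#' @param motif_bits_per_target reserved motif bits per gene (default 32).
#' @param base_bit_rate background bit probability (default 0.02).
#' @param structure_noise_rate independent bit-flip probability (default
#'   0.02).
#' @param signature_noise_sd Gaussian noise SD on signatures (default 0.5;
#'   templates have unit variance).
#' @param decoy_compound_fraction fraction of decoy compounds (default 0.1).
#' @param seed integer seed (default 1).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_compounds = 200, n_genes = 30, n_pathways = 6,
                       genes_per_pathway = 5, n_bits = 2048, sig_dim = 978,
                       replicates_per_gene = 1,
                       pert_types = c("knock-down", "knock-out",
                                      "over-expression"),
                       n_sig_per_compound = 3,
                       motif_bits_per_target = 32, base_bit_rate = 0.02,
                       structure_noise_rate = 0.02, signature_noise_sd = 0.5,
                       decoy_compound_fraction = 0.1, seed = 1L) {
  cfg <- list(n_compounds = as.integer(n_compounds),
              n_genes = as.integer(n_genes),
              n_pathways = as.integer(n_pathways),
              genes_per_pathway = as.integer(genes_per_pathway),
              n_bits = as.integer(n_bits), sig_dim = as.integer(sig_dim),
              replicates_per_gene = as.integer(replicates_per_gene),
              pert_types = pert_types,
              n_sig_per_compound = as.integer(n_sig_per_compound),
              motif_bits_per_target = as.integer(motif_bits_per_target),
              base_bit_rate = base_bit_rate,
              structure_noise_rate = structure_noise_rate,
              signature_noise_sd = signature_noise_sd,
              decoy_compound_fraction = decoy_compound_fraction,
              seed = as.integer(seed))
  stopifnot(cfg$n_compounds >= 3, cfg$n_genes >= 1, cfg$n_pathways >= 1,
            cfg$genes_per_pathway >= 1, cfg$n_bits >= 1, cfg$sig_dim >= 1,
            cfg$replicates_per_gene >= 1, cfg$n_sig_per_compound >= 1,
            cfg$motif_bits_per_target >= 1)
  if (cfg$n_genes < cfg$n_pathways)
    stop("need at least as many genes as pathways")
  if (cfg$n_pathways * cfg$genes_per_pathway > cfg$n_genes)
    stop("disjoint pathways need n_pathways * genes_per_pathway <= n_genes")
  if (cfg$n_genes > cfg$sig_dim)
    stop("target genes are drawn from the signature gene universe; ",
         "n_genes must not exceed sig_dim")
  if (cfg$motif_bits_per_target * cfg$n_genes > cfg$n_bits)
    stop("motif bit demand (", cfg$motif_bits_per_target * cfg$n_genes,
         ") exceeds n_bits (", cfg$n_bits, ")")
  for (r in c("base_bit_rate", "structure_noise_rate",
              "decoy_compound_fraction"))
    if (cfg[[r]] < 0 || cfg[[r]] > 1) stop("'", r, "' must lie in [0, 1]")
  if (cfg$signature_noise_sd < 0) stop("'signature_noise_sd' must be >= 0")
  if (!all(cfg$pert_types %in% c("knock-down", "knock-out",
                                 "over-expression")))
    stop("unknown perturbation type in 'pert_types'")
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic corpus with a planted target linkage
#'
#' Draws a full corpus -- compound fingerprints, replicate compound
#' signatures, genetic-perturbation signatures, disjoint pathway gene sets
#' and MoA truth labels -- from the generative model described in
#' [sim_config()].  Fully reproducible given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return An object of class `sim_corpus`: list with elements `compounds`
#'   (data.frame `compound_id`, `target_gene`, `is_decoy`), `fingerprints`
#'   (0/1 matrix), `compound_signatures` and `gp_signatures`
#'   ([signature_matrix] objects), `pathways` (`pathway_collection`),
#'   `truth` (named list, non-decoy compounds only), `target_map`, and
#'   `config`.
#' @export
simulate_corpus <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, .simulate_corpus_impl(config))
}

.simulate_corpus_impl <- function(cfg) {
  gene_universe <- sprintf("G%04d", seq_len(cfg$sig_dim))
  genes <- gene_universe[seq_len(cfg$n_genes)]

  # pathways partition the first n_pathways * genes_per_pathway genes
  in_pathway <- split(
    genes[seq_len(cfg$n_pathways * cfg$genes_per_pathway)],
    rep(seq_len(cfg$n_pathways), each = cfg$genes_per_pathway))
  names(in_pathway) <- sprintf("P%02d", seq_len(cfg$n_pathways))
  pathways <- pathway_collection(in_pathway, source_name = "synthetic")
  targetable <- unlist(in_pathway, use.names = FALSE)
  gene_to_pathway <- stats::setNames(
    rep(names(in_pathway), lengths(in_pathway)), targetable)

  # latent signature template and private motif bits per gene
  templates <- matrix(stats::rnorm(cfg$sig_dim * cfg$n_genes),
                      cfg$sig_dim, cfg$n_genes,
                      dimnames = list(gene_universe, genes))
  motif_pos <- matrix(sample.int(cfg$n_bits,
                                 cfg$motif_bits_per_target * cfg$n_genes),
                      cfg$motif_bits_per_target, cfg$n_genes,
                      dimnames = list(NULL, genes))

  n_decoy <- round(cfg$decoy_compound_fraction * cfg$n_compounds)
  n_active <- cfg$n_compounds - n_decoy
  if (n_active < 2) stop("fewer than 2 non-decoy compounds")
  ids <- sprintf("C%04d", seq_len(cfg$n_compounds))
  is_decoy <- c(rep(FALSE, n_active), rep(TRUE, n_decoy))
  target <- c(sample(targetable, n_active, replace = TRUE),
              rep(NA_character_, n_decoy))

  # fingerprints: motif + background, then independent bit flips
  fp <- matrix(stats::rbinom(cfg$n_compounds * cfg$n_bits, 1,
                             cfg$base_bit_rate),
               cfg$n_compounds, cfg$n_bits, dimnames = list(ids, NULL))
  for (i in seq_len(n_active)) fp[i, motif_pos[, target[i]]] <- 1L
  if (cfg$structure_noise_rate > 0) {
    flips <- matrix(stats::rbinom(length(fp), 1, cfg$structure_noise_rate),
                    nrow(fp), ncol(fp))
    fp <- abs(fp - flips)
    storage.mode(fp) <- "integer"
  }

  # replicate compound signatures: template + noise; decoys pure noise
  ks <- cfg$n_sig_per_compound
  sig_cols <- matrix(0, cfg$sig_dim, cfg$n_compounds * ks)
  cn <- character(cfg$n_compounds * ks)
  pid <- character(cfg$n_compounds * ks)
  j <- 0L
  for (i in seq_len(cfg$n_compounds)) {
    base <- if (is_decoy[i]) 0 else templates[, target[i]]
    for (r in seq_len(ks)) {
      j <- j + 1L
      sig_cols[, j] <- base +
        stats::rnorm(cfg$sig_dim,
                     sd = if (is_decoy[i]) 1 else cfg$signature_noise_sd)
      cn[j] <- sprintf("%s_rep%d", ids[i], r)
      pid[j] <- ids[i]
    }
  }
  dimnames(sig_cols) <- list(gene_universe, cn)
  compound_signatures <- signature_matrix(
    sig_cols,
    data.frame(sample_id = cn, perturbagen_id = pid, pert_type = "compound",
               target_gene = "", cell_line = "", stringsAsFactors = FALSE))

  # GP signatures: per gene, per pert type, per replicate
  n_gp <- cfg$n_genes * length(cfg$pert_types) * cfg$replicates_per_gene
  gp_cols <- matrix(0, cfg$sig_dim, n_gp)
  gn <- tg <- pt <- character(n_gp)
  j <- 0L
  for (g in genes) for (p in cfg$pert_types)
    for (r in seq_len(cfg$replicates_per_gene)) {
      j <- j + 1L
      gp_cols[, j] <- templates[, g] +
        stats::rnorm(cfg$sig_dim, sd = cfg$signature_noise_sd)
      gn[j] <- sprintf("%s_%s_rep%d", g, gsub("-", "", p), r)
      tg[j] <- g; pt[j] <- p
    }
  dimnames(gp_cols) <- list(gene_universe, gn)
  gp_signatures <- signature_matrix(
    gp_cols,
    data.frame(sample_id = gn, perturbagen_id = tg, pert_type = pt,
               target_gene = tg, cell_line = "", stringsAsFactors = FALSE))

  truth <- lapply(which(!is_decoy), function(i)
    unname(gene_to_pathway[target[i]]))
  names(truth) <- ids[!is_decoy]

  corpus <- structure(list(
    compounds = data.frame(compound_id = ids, target_gene = target,
                           is_decoy = is_decoy, stringsAsFactors = FALSE),
    fingerprints = fp,
    compound_signatures = compound_signatures,
    gp_signatures = gp_signatures,
    pathways = pathways,
    truth = truth,
    target_map = stats::setNames(target[!is_decoy], ids[!is_decoy]),
    config = cfg), class = "sim_corpus")
  validate_sim_corpus(corpus)
  corpus
}

#' Validate the internal consistency of a synthetic corpus
#'
#' Checks the structural invariants: every non-decoy compound's target gene
#' appears in at least one pathway and has at least one GP column, and all
#' dimensions agree with the configuration.
#'
#' @param corpus a `sim_corpus`.
#' @return `corpus`, invisibly; errors describe the violated invariant.
#' @export
validate_sim_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "sim_corpus"))
  cfg <- corpus$config
  act <- corpus$compounds[!corpus$compounds$is_decoy, ]
  gp_genes <- unique(corpus$gp_signatures$column_meta$target_gene)
  path_genes <- unique(unlist(corpus$pathways, use.names = FALSE))
  if (!all(act$target_gene %in% gp_genes))
    stop("non-decoy compound target(s) without GP columns")
  if (!all(act$target_gene %in% path_genes))
    stop("non-decoy compound target(s) not covered by any pathway")
  if (nrow(corpus$fingerprints) != cfg$n_compounds ||
      ncol(corpus$fingerprints) != cfg$n_bits)
    stop("fingerprint matrix dimensions disagree with config")
  if (nrow(corpus$compound_signatures$values) != cfg$sig_dim ||
      nrow(corpus$gp_signatures$values) != cfg$sig_dim)
    stop("signature dimension disagrees with config")
  if (ncol(corpus$compound_signatures$values) !=
      cfg$n_compounds * cfg$n_sig_per_compound)
    stop("compound signature count disagrees with config")
  if (length(corpus$pathways) != cfg$n_pathways)
    stop("pathway count disagrees with config")
  if (!setequal(names(corpus$truth), act$compound_id))
    stop("truth labels must cover exactly the non-decoy compounds")
  invisible(corpus)
}

#' @export
print.sim_corpus <- function(x, ...) {
  cat("sim_corpus: ", nrow(x$compounds), " compounds (",
      sum(x$compounds$is_decoy), " decoys), ",
      length(unique(x$gp_signatures$column_meta$target_gene)),
      " GP genes, ", length(x$pathways), " pathways, seed ",
      x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic corpus as the pipeline's file dialects
#'
#' Emits exactly the formats the I/O layer defines -- GCT (+ metadata
#' sidecars) for both signature matrices, GMT for pathways, TSV for
#' fingerprints, truth labels and target assignments, and the generator
#' configuration as YAML -- so every downstream stage runs unmodified on
#' the files.
#'
#' @param corpus a `sim_corpus`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @seealso [corpus_from_files()]
#' @export
corpus_to_files <- function(corpus, dir) {
  stopifnot(inherits(corpus, "sim_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_signature_gct(corpus$compound_signatures,
                      file.path(dir, "compound_signatures.gct"))
  write_signature_gct(corpus$gp_signatures,
                      file.path(dir, "gp_signatures.gct"))
  write_gmt(corpus$pathways, file.path(dir, "pathways.gmt"))
  write_fingerprints(corpus$fingerprints, file.path(dir, "fingerprints.tsv"))
  write_moa_truth(corpus$truth, file.path(dir, "truth.tsv"))
  utils::write.table(corpus$compounds, file.path(dir, "compounds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(corpus$config), file.path(dir, "sim_config.yaml"))
  invisible(dir)
}

#' Read a synthetic corpus back from its file tree
#'
#' @param dir directory written by [corpus_to_files()].
#' @return A `sim_corpus` (numeric values at the writer's 10-significant-
#'   digit precision).
#' @export
corpus_from_files <- function(dir) {
  cfg <- do.call(sim_config, yaml::read_yaml(file.path(dir,
                                                       "sim_config.yaml")))
  compounds <- utils::read.delim(file.path(dir, "compounds.tsv"),
                                 stringsAsFactors = FALSE)
  compounds$target_gene <- as.character(compounds$target_gene)
  compounds$target_gene[compounds$is_decoy] <- NA_character_
  corpus <- structure(list(
    compounds = compounds,
    fingerprints = read_fingerprints(file.path(dir, "fingerprints.tsv")),
    compound_signatures = read_signature_gct(
      file.path(dir, "compound_signatures.gct")),
    gp_signatures = read_signature_gct(file.path(dir, "gp_signatures.gct")),
    pathways = read_gmt(file.path(dir, "pathways.gmt"),
                        source_name = "synthetic"),
    truth = read_moa_truth(file.path(dir, "truth.tsv")),
    target_map = NULL,
    config = cfg), class = "sim_corpus")
  corpus$target_map <- stats::setNames(
    compounds$target_gene[!compounds$is_decoy],
    compounds$compound_id[!compounds$is_decoy])
  validate_sim_corpus(corpus)
  corpus
}
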