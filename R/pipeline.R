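#' Validate a pipeline configuration
#'
#' @param config Named list (or YAML path) of run settings. Recognized
#'   thresholds: `ambiguity_threshold` (default 0.2), `high_pp` (0.9),
#'   `long_branch` (0.7), `cluster_identity` (0.99), `max_gap_fraction`
#'   (0.25), plus `seed`, `out_dir`, input paths and stage options.
#' @return The validated config list with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(ambiguity_threshold = 0.2, high_pp = 0.9, long_branch = 0.7,
                   cluster_identity = 0.99, max_gap_fraction = 0.25,
                   window = 3, seed = 1)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  in01 <- c("ambiguity_threshold", "high_pp", "cluster_identity", "max_gap_fraction")
  for (nm in in01) {
    v <- config[[nm]]
    if (!is.numeric(v) || v <= 0 || v >= 1) {
      if (!(nm %in% c("max_gap_fraction") && v == 1)) {
        stop(sprintf("validation error: %s must lie in (0, 1), got %s", nm, v))
      }
    }
  }
  if (!is.numeric(config$long_branch) || config$long_branch <= 0) {
    stop("validation error: long_branch must be > 0")
  }
  if (is.null(config$out_dir)) stop("validation error: out_dir is required")
  for (key in c("alignment", "tree", "model_file", "gene_table")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]])) {
      stop(sprintf("validation error: %s file '%s' does not exist", key, config[[key]]))
    }
  }
  config
}

#' Run the reconstruction pipeline
#'
#' Executes the requested stages in dependency order on the configured
#' inputs: `curate` (gap/ambiguity filtering, long-branch removal),
#' `loglik`, `fit` (FreeRate), `reconstruct`, `summarize`, `classify`
#' (signature schemes per clade), `diff` (ancestor comparison),
#' `neighborhood`, or `simulate` (generate inputs first). All outputs land
#' under `out_dir` together with a manifest recording input checksums, the
#' config, the package version and the seed; re-running with identical
#' inputs and seed reproduces the outputs byte for byte.
#'
#' @param config Named list or YAML path; see [validate_config]. Key
#'   `stages` selects stages (default: everything applicable).
#' @return Invisibly, the manifest list (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- cfg$stages
  if (is.null(stages)) {
    stages <- c(if (is.null(cfg$alignment)) "simulate",
                "curate", "loglik", "reconstruct", "summarize",
                if (!is.null(cfg$clades)) "classify",
                if (!is.null(cfg$gene_table)) "neighborhood")
  }
  outputs <- character(0)
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  if ("simulate" %in% stages) {
    n_leaves <- cfg$sim_leaves %||% 16
    n_sites <- cfg$sim_sites %||% 300
    set.seed(cfg$seed)
    tree <- ape::rtree(n_leaves, br = function(n) stats::runif(n, 0.02, 0.3))
    tree <- label_internal_nodes(tree)
    model <- lg_model()
    sim <- simulate_alignment(tree, model, n_sites, seed = cfg$seed)
    cfg$alignment <- file.path(cfg$out_dir, "simulated.fasta")
    cfg$tree <- file.path(cfg$out_dir, "simulated.nwk")
    write_fasta(sim$alignment, cfg$alignment)
    write_newick(sim$tree, cfg$tree)
    outputs <- c(outputs, cfg$alignment, cfg$tree)
    note("simulate: %d leaves, %d sites, seed %d", n_leaves, n_sites, cfg$seed)
  }

  if (is.null(cfg$alignment) || is.null(cfg$tree)) {
    stop("stage error [inputs]: alignment and tree are required")
  }
  aln <- read_fasta(cfg$alignment)
  tree <- read_newick(cfg$tree)

  if ("curate" %in% stages) {
    aln <- filter_sequences(aln, cfg$max_gap_fraction, drop_ambiguous = TRUE)
    removed <- attr(aln, "removals")
    lb <- detect_long_branches(tree, cfg$long_branch)
    drop <- union(removed$id, lb$leaves)
    drop <- intersect(drop, tree$tip.label)
    if (length(drop) && length(drop) < length(tree$tip.label) - 2) {
      tree <- ape::drop.tip(tree, drop)
      tree <- label_internal_nodes(tree)
    }
    aln <- subset_rows(aln, intersect(rownames(aln), tree$tip.label))
    curated <- file.path(cfg$out_dir, "curated.fasta")
    write_fasta(aln, curated)
    rep_path <- file.path(cfg$out_dir, "curation_report.tsv")
    utils::write.table(rbind(removed,
                             if (length(lb$leaves))
                               data.frame(id = lb$leaves,
                                          reason = sprintf("pendant branch > %.2f", cfg$long_branch))),
                       rep_path, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, curated, rep_path)
    note("curate: %d sequences kept, %d removed", nrow(aln), length(drop))
  }

  model <- if (!is.null(cfg$model_file)) read_model_file(cfg$model_file) else lg_model(empirical_frequencies(aln))

  if ("fit" %in% stages) {
    K <- cfg$freerate_k %||% 2
    fit <- fit_freerate(tree, aln, model$S, model$pi, K = K)
    model <- fit$model
    mf <- file.path(cfg$out_dir, "fitted.model")
    write_model_file(model, mf)
    outputs <- c(outputs, mf)
    note("fit: K=%d, logL=%.4f", K, fit$logLik)
  }

  if ("loglik" %in% stages) {
    ll <- prune_loglik(tree, aln, model)
    llp <- file.path(cfg$out_dir, "site_loglik.tsv")
    utils::write.table(data.frame(site = seq_along(ll$site_loglik),
                                  loglik = ll$site_loglik),
                       llp, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, llp)
    note("loglik: total %.4f", ll$total)
  }

  asr <- NULL
  if (any(c("reconstruct", "summarize", "diff") %in% stages)) {
    nodes <- cfg$nodes
    asr <- marginal_posteriors(tree, aln, model, nodes = nodes,
                               ambiguity_threshold = cfg$ambiguity_threshold)
    st <- as_state_table(asr)
    stp <- file.path(cfg$out_dir, "ancestral_states.tsv")
    write_state_table(st, stp)
    fa <- file.path(cfg$out_dir, "ancestors_ml.fasta")
    ml <- vapply(asr$nodes, function(nd) ml_sequence(asr, nd)$sequence, character(1))
    write_fasta(stats::setNames(ml, asr$nodes), fa)
    alt <- vapply(asr$nodes, function(nd)
      altall_sequence(asr, nd, cfg$ambiguity_threshold)$sequence, character(1))
    faa <- file.path(cfg$out_dir, "ancestors_altall.fasta")
    write_fasta(stats::setNames(alt, paste0(asr$nodes, "_AltALL")), faa)
    outputs <- c(outputs, stp, fa, faa)
    note("reconstruct: %d node(s)", length(asr$nodes))
  }

  if ("summarize" %in% stages && !is.null(asr)) {
    sm <- summary(asr)
    smp <- file.path(cfg$out_dir, "pp_summary.tsv")
    utils::write.table(sm, smp, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, smp)
    note("summarize: %d ancestors", nrow(sm))
  }

  if ("classify" %in% stages) {
    if (is.null(cfg$reference_id) || is.null(cfg$clades) || is.null(cfg$scheme)) {
      stop("stage error [classify]: reference_id, clades and scheme required")
    }
    rmap <- build_reference_map(aln, cfg$reference_id)
    clades <- assign_clades(tree, unlist(cfg$clades))
    scheme <- read_scheme(cfg$scheme)
    stats_df <- clade_signature_stats(aln, clades, scheme, rmap)
    cp <- file.path(cfg$out_dir, "clade_signatures.tsv")
    utils::write.table(stats_df, cp, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, cp)
    note("classify: %d clades against '%s'", nrow(stats_df), scheme$name)
  }

  if ("diff" %in% stages && !is.null(asr) && length(asr$nodes) >= 2) {
    pair <- cfg$diff_nodes %||% asr$nodes[1:2]
    dr <- ancestor_diff(asr, asr, node1 = pair[1], node2 = pair[2],
                        high_pp = cfg$high_pp)
    dp <- file.path(cfg$out_dir, "ancestor_diff.tsv")
    utils::write.table(as.data.frame(dr), dp, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, dp)
    note("diff: %s vs %s, %d differing sites, identity %.1f%%",
         pair[1], pair[2], nrow(dr), attr(dr, "identity"))
  }

  if ("neighborhood" %in% stages && !is.null(cfg$gene_table)) {
    gt <- read_gene_table(cfg$gene_table)
    pr <- pair_transporters(gt, cfg$enzyme_labels %||% "aa_metabolism",
                            window = cfg$window)
    np <- file.path(cfg$out_dir, "neighborhood.tsv")
    utils::write.table(pr$by_clade, np, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, np)
    note("neighborhood: fraction %.4f", pr$fraction)
  }

  inputs <- unique(stats::na.omit(unlist(cfg[c("alignment", "tree", "model_file", "gene_table")])))
  manifest <- list(
    package = "asrkit",
    version = as.character(utils::packageVersion("asrkit")),
    seed = cfg$seed,
    stages = stages,
    config = cfg[setdiff(names(cfg), "stages")],
    inputs = lapply(inputs, function(p) list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = outputs,
    log = log)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
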