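# End-to-end orchestration of a synthetic-demo or user-supplied analysis run:
# simulate -> spacing -> scan -> discover -> classify -> model, with a JSON
# manifest (configuration + package version + seeds) written alongside every
# output so each numeric table is reproducible from the manifest alone.

default_config <- function() {
  list(
    seed = 1L,
    stages = c("simulate", "spacing", "scan", "discover", "classify", "model"),
    simulate = list(
      n_pos = 40L, n_neg = 40L, length_range = c(500L, 1500L),
      cpg_per_kbp = 80, gc = 0.6,
      motif = "CGCGC", pos_in_fraction = 0.8, neg_in_fraction = 0.3,
      motif_count = 3L),
    spacing = list(n_perm = 199L, d_lo = 8L, d_hi = 10L, max_d = 200L),
    scan = list(strands = "both", window = 100L),
    discover = list(k_min = 4L, k_max = 6L, e_threshold = 0.05,
                    gap_orders = 5),
    classify = list(n_per_class = 3L),
    model = list(
      n = 4000L,
      coef = c(`(Intercept)` = 1, PA = -2, Rloop = -0.4, Cfp1 = -0.8,
               H3K4me3 = -1.5, Motif = -1.2),
      prevalence = c(PA = 0.45, Rloop = 0.55, Cfp1 = 0.5, H3K4me3 = 0.5,
                     Motif = 0.6))
  )
}

validate_config <- function(config) {
  known <- names(default_config())
  extra <- setdiff(names(config), known)
  if (length(extra))
    stop("unknown config entries: ", paste(extra, collapse = ", "), call. = FALSE)
  if (!is.null(config$seed) && (!is.numeric(config$seed) || length(config$seed) != 1))
    stop("config$seed must be a single integer", call. = FALSE)
  if (!is.null(config$stages)) {
    bad <- setdiff(config$stages, default_config()$stages)
    if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
  }
  invisible(TRUE)
}

merge_config <- function(config) {
  def <- default_config()
  for (nm in names(config)) {
    if (is.list(def[[nm]]) && is.list(config[[nm]])) {
      for (k in names(config[[nm]])) def[[nm]][[k]] <- config[[nm]][[k]]
    } else def[[nm]] <- config[[nm]]
  }
  def
}

#' Run the synthetic-demo analysis pipeline
#'
#' Executes the configured stages in dependency order on seed-deterministic
#' synthetic data: sequence simulation (a motif-enriched "positive" set
#' emulating unmethylated CGIs and a depleted "negative" set), CpG-spacing
#' range tests, motif presence/density statistics with a shuffle control,
#' discriminative motif discovery, layout classification, and the
#' multi-factor logistic analysis. Every run writes `manifest.json` (full
#' configuration, package version, seed) plus one TSV per stage; re-running
#' with the same config yields byte-identical tables.
#'
#' @param config nested list overriding the defaults (see
#'   `cgisig:::default_config()`); may be a path to a YAML file.
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the per-stage results and output paths.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  validate_config(config)
  cfg <- merge_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  results <- list()

  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  pos <- neg <- NULL
  if ("simulate" %in% cfg$stages) {
    results$simulate <- run_stage("simulate", function() {
      sc <- cfg$simulate
      pos <<- sim_cgi_seqs(sc$n_pos, sc$length_range, sc$cpg_per_kbp, sc$gc,
                           motifs = list(list(pattern = sc$motif,
                                              count = sc$motif_count,
                                              in_fraction = sc$pos_in_fraction)),
                           seed = derive_seed(seed, 101))
      neg <- sim_cgi_seqs(sc$n_neg, sc$length_range, sc$cpg_per_kbp, sc$gc,
                          motifs = list(list(pattern = sc$motif,
                                             count = sc$motif_count,
                                             in_fraction = sc$neg_in_fraction)),
                          seed = derive_seed(seed, 102))
      names(neg$seqs) <- sub("^sim", "neg", names(neg$seqs))
      neg$truth$seq_id <- names(neg$seqs)
      neg <<- neg
      write_fasta(pos$seqs, file.path(out_dir, "pos.fasta"))
      write_fasta(neg$seqs, file.path(out_dir, "neg.fasta"))
      write_tsv_report(rbind(cbind(group = "pos", pos$truth),
                             cbind(group = "neg", neg$truth)),
                       file.path(out_dir, "simulate_truth.tsv"),
                       params = list(seed = seed))
      list(pos = pos, neg = neg)
    })
  }
  if (is.null(pos)) stop("pipeline requires the 'simulate' stage", call. = FALSE)
  all_seqs <- c(pos$seqs, neg$seqs)
  groups <- rep(c("pos", "neg"), c(length(pos$seqs), length(neg$seqs)))

  if ("spacing" %in% cfg$stages) {
    results$spacing <- run_stage("spacing", function() {
      sp <- cfg$spacing
      tests <- lapply(seq_along(all_seqs), function(i)
        range_enrichment_test(all_seqs[[i]], sp$d_lo, sp$d_hi, sp$n_perm,
                              derive_seed(seed, 200 + i)))
      df <- data.frame(seq_id = names(all_seqs), group = groups,
                       statistic = vapply(tests, `[[`, numeric(1), "statistic"),
                       p = vapply(tests, `[[`, numeric(1), "p"))
      write_tsv_report(df, file.path(out_dir, "spacing_range_tests.tsv"),
                       params = list(seed = seed, d_lo = sp$d_lo,
                                     d_hi = sp$d_hi, n_perm = sp$n_perm))
      df
    })
  }

  if ("scan" %in% cfg$stages) {
    results$scan <- run_stage("scan", function() {
      motif <- cfg$simulate$motif
      stats_df <- rbind(motif_stats(pos$seqs, motif, category = "pos"),
                        motif_stats(neg$seqs, motif, category = "neg"))
      red <- shuffle_reduction(pos$seqs, motif, seed = derive_seed(seed, 300))
      stats_df$shuffle_reduction_pct <-
        c(red$occurrence_reduction_pct, NA_real_)
      write_tsv_report(stats_df, file.path(out_dir, "motif_stats.tsv"),
                       params = list(seed = seed, motif = motif))
      stats_df
    })
  }

  if ("discover" %in% cfg$stages) {
    results$discover <- run_stage("discover", function() {
      dc <- cfg$discover
      rep_ <- discriminative_search(pos$seqs, neg$seqs, dc$k_min, dc$k_max,
                                    dc$e_threshold)
      rep_$characteristic <- characteristic_motif(rep_, dc$e_threshold,
                                                  dc$gap_orders)
      write_tsv_report(rep_$results, file.path(out_dir, "discovery.tsv"),
                       params = list(seed = seed, k_min = dc$k_min,
                                     k_max = dc$k_max,
                                     n_candidates = rep_$n_candidates,
                                     characteristic =
                                       if (is.null(rep_$characteristic)) "none"
                                       else rep_$characteristic$motif))
      rep_
    })
  }

  if ("classify" %in% cfg$stages) {
    results$classify <- run_stage("classify", function() {
      lay <- sim_layout(cfg$classify$n_per_class, seed = derive_seed(seed, 400))
      cls <- classify_cgis(lay$cgis, lay$transcripts)
      cls$truth_class <- lay$truth$class[match(cls$cgi_id, lay$truth$cgi_id)]
      write_tsv_report(cls, file.path(out_dir, "classification.tsv"),
                       params = list(seed = seed))
      cls
    })
  }

  if ("model" %in% cfg$stages) {
    results$model <- run_stage("model", function() {
      mc <- cfg$model
      sim <- sim_factor_table(mc$n, mc$coef, mc$prevalence,
                              seed = derive_seed(seed, 500))
      factors <- names(mc$prevalence)
      rank_df <- deviance_ranking(sim$table, factors)
      net <- interaction_network(sim$table, factors)
      write_tsv_report(rank_df, file.path(out_dir, "deviance_ranking.tsv"),
                       params = list(seed = seed, n = mc$n))
      write_tsv_report(net, file.path(out_dir, "interactions.tsv"),
                       params = list(seed = seed, n = mc$n,
                                     m = attr(net, "m")))
      list(ranking = rank_df, network = net, table = sim$table)
    })
  }

  manifest <- list(package = "cgisig",
                   version = as.character(utils::packageVersion("cgisig")),
                   seed = seed, config = cfg,
                   outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(results, list(out_dir = out_dir, manifest = manifest)))
}
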