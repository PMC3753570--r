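#' Learn the complete model family from SIF + MIDAS files
#'
#' End-to-end pipeline: read the network and dataset, assign roles from the
#' MIDAS header, compress, expand into the candidate gate hypergraph, find
#' the lexicographic (MSE, size) optimum and enumerate every model within
#' tolerance. Writes `hypergraph.csv`, `family.csv` (+ `.meta.json`) and
#' `run_config.json` into `out_dir`; outputs are deterministic, so two runs
#' on the same inputs are byte-identical.
#'
#' @param sif_path,midas_path input files.
#' @param out_dir output directory (created if needed).
#' @param time acquisition time to fit (`NULL` = earliest positive).
#' @param fit_tolerance,size_bound,precision,max_models see
#'   [enumeration_config()].
#' @param max_gate_size gate-size cap for expansion (default 4).
#' @param normalize `"minmax"` or `"passthrough"`.
#' @return Invisibly, a list with the in-memory `hypergraph`, `family`,
#'   `dataset` and the output file paths.
#' @export
run_learn <- function(sif_path, midas_path, out_dir,
                      time = NULL, fit_tolerance = 0, size_bound = "optimal",
                      max_gate_size = 4, precision = 2,
                      normalize = c("minmax", "passthrough"),
                      max_models = 1e6) {
  normalize <- match.arg(normalize)
  net <- read_sif(sif_path)
  md <- read_midas(midas_path)
  net <- set_roles(net, md$roles)
  dataset <- normalize_dataset(select_time(md, time), normalize)
  hg <- expand_pkn(compress_pkn(net), max_gate_size)
  config <- enumeration_config(fit_tolerance = fit_tolerance,
                               size_bound = size_bound, precision = precision,
                               max_models = max_models)
  family <- enumerate_models(hg, dataset, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(hypergraph = file.path(out_dir, "hypergraph.csv"),
                family = file.path(out_dir, "family.csv"),
                config = file.path(out_dir, "run_config.json"))
  write_hypergraph(hg, paths$hypergraph)
  write_family(family, paths$family)
  jsonlite::write_json(list(sif = sif_path, midas = midas_path,
                            time = dataset$time,
                            fit_tolerance = fit_tolerance,
                            size_bound = size_bound,
                            max_gate_size = max_gate_size,
                            precision = precision, normalize = normalize,
                            max_models = max_models, backend = "native"),
                       paths$config, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list(hypergraph = hg, family = family, dataset = dataset,
                 paths = paths))
}

#' Structural analysis of a learned family
#'
#' Writes the hyperedge frequency report and the mutually exclusive module
#' pairs for a family produced by [run_learn()].
#'
#' @param family a `model_family` (or the list returned by [run_learn()]).
#' @param out_dir output directory.
#' @return Invisibly, list with `frequencies` and `exclusive_pairs`.
#' @export
run_analyze <- function(family, out_dir) {
  if (!inherits(family, "model_family")) family <- family$family
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  freq <- hyperedge_frequencies(family)
  pairs <- mutually_exclusive_pairs(family)
  utils::write.csv(freq, file.path(out_dir, "hyperedge_frequencies.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(pairs, file.path(out_dir, "exclusive_pairs.csv"),
                   row.names = FALSE, quote = TRUE)
  invisible(list(frequencies = freq, exclusive_pairs = pairs))
}

#' Behavior (GTT) analysis of a learned family
#'
#' Groups the family by Global Truth Table, extracts core predictions and
#' (when more than one behavior exists) clusters the behaviors, writing
#' `gtt_groups.csv`, `core_predictions.csv` and `gtt_dendrogram.nwk`.
#'
#' @param family a `model_family` (or [run_learn()] result).
#' @param out_dir output directory.
#' @param cap input-count cap for the GTT grid.
#' @return Invisibly, list with `gtts`, `core` and `clustering` (`NULL` for
#'   a single behavior).
#' @export
run_behaviors <- function(family, out_dir, cap = 20) {
  if (!inherits(family, "model_family")) family <- family$family
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gtts <- group_by_gtt(family, cap = cap)
  core <- core_predictions(gtts)
  write_gtts(gtts, file.path(out_dir, "gtt_groups.csv"))
  utils::write.csv(core$core, file.path(out_dir, "core_predictions.csv"),
                   row.names = FALSE, quote = FALSE)
  clustering <- NULL
  if (length(gtts) >= 2) {
    clustering <- cluster_gtts(gtts)
    writeLines(clustering$newick, file.path(out_dir, "gtt_dendrogram.nwk"))
  }
  invisible(list(gtts = gtts, core = core, clustering = clustering))
}

#' Discriminating-experiment design for a learned family
#'
#' Computes the minimal discriminating condition set over the family's
#' behaviors and the ranked simplest single experiments, writing
#' `discriminating_set.csv` and `best_experiments.csv`.
#'
#' @param family a `model_family` (or [run_learn()] result).
#' @param out_dir output directory.
#' @param mode `"exact"` or `"greedy"` set cover.
#' @param cap input-count cap for the GTT grid.
#' @return Invisibly, list with `gtts`, `cover` and `best` (both `NULL` when
#'   the family has a single behavior).
#' @export
run_design <- function(family, out_dir, mode = "exact", cap = 20) {
  if (!inherits(family, "model_family")) family <- family$family
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gtts <- group_by_gtt(family, cap = cap)
  cover <- NULL; best <- NULL
  if (length(gtts) >= 2) {
    cover <- minimal_discriminating_set(gtts, mode = mode)
    best <- best_single_experiments(gtts)
    write_experiments(cover, file.path(out_dir, "discriminating_set.csv"))
    write_experiments(best, file.path(out_dir, "best_experiments.csv"))
  }
  invisible(list(gtts = gtts, cover = cover, best = best))
}

#' Load the published liver (HepG2) benchmark from local files
#'
#' The pro-growth / inflammatory liver-cell case study (15 measured species,
#' 64 conditions, 130 candidate hyperedges after expansion) is distributed
#' with the CellNOpt project, not with this package. Point this loader at a
#' directory containing the benchmark's SIF network and MIDAS dataset to run
#' the full pipeline on it.
#'
#' @param dir directory holding one `*.sif` and one `*.csv` file.
#' @return list with `pkn` (roles assigned from the MIDAS header) and
#'   `midas` (a `midas_data`).
#' @export
load_liver_benchmark <- function(dir) {
  sif <- list.files(dir, "\\.sif$", full.names = TRUE)
  csv <- list.files(dir, "\\.csv$", full.names = TRUE)
  if (length(sif) != 1 || length(csv) != 1)
    stop("benchmark files not found under '", dir,
         "': expected exactly one .sif and one .csv (obtain them from the ",
         "CellNOpt project distribution)")
  net <- read_sif(sif)
  md <- read_midas(csv)
  list(pkn = set_roles(net, md$roles), midas = md)
}
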