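#' Configuration for family enumeration
#'
#' @param fit_tolerance fraction `eps >= 0`; models with
#'   `MSE <= (1 + eps) * MSE_opt` qualify (multiplicative tolerance on the
#'   fit, mirroring a "within 10 percent of the optimum" reading of
#'   experimental error).
#' @param size_bound integer bound on model size, or `"optimal"` to use the
#'   size of the lexicographic optimum (the usual choice: tolerance on fit,
#'   none on parsimony).
#' @param precision discretization digits for exact scoring (default 2).
#' @param backend `"native"` (complete branch-and-bound, the reference
#'   implementation) or `"external"` (reserved for an external solver; not
#'   configured in this installation).
#' @param max_models safety cap on the family size; enumeration stops with an
#'   error asking for a tighter tolerance when exceeded.
#' @return An `enumeration_config` list.
#' @export
enumeration_config <- function(fit_tolerance = 0, size_bound = "optimal",
                               precision = 2, backend = c("native", "external"),
                               max_models = 1e6) {
  backend <- match.arg(backend)
  stopifnot(fit_tolerance >= 0, precision >= 0, max_models >= 1)
  if (!identical(size_bound, "optimal"))
    stopifnot(is.numeric(size_bound), size_bound >= 0)
  structure(list(fit_tolerance = fit_tolerance, size_bound = size_bound,
                 precision = precision, backend = backend,
                 max_models = max_models), class = "enumeration_config")
}

check_backend <- function(config) {
  if (config$backend == "external")
    stop("no external solver backend is configured; use backend = \"native\"")
}

search_args <- function(hg, dataset, precision, max_steps) {
  if (nrow(hg$edges) == 0) stop("hypergraph has no candidate gates")
  if (!all(dataset$readouts %in% hg$nodes))
    stop("dataset readouts not all present in hypergraph nodes")
  obs <- scale_obs(dataset, precision)
  if (all(is.na(obs))) stop("dataset has no non-missing measurements")
  enc <- gate_encoding(hg)
  if (is.null(max_steps)) max_steps <- 3L * enc$N
  list(enc = enc,
       clamps = build_clamps(hg, dataset$stim, dataset$inhib),
       obs = obs,
       readout_idx = match(dataset$readouts, hg$nodes) - 1L,
       pscale = 10^precision,
       n_compared = sum(!is.na(obs)),
       max_steps = as.integer(max_steps))
}

#' Find the lexicographic (MSE, size) optimum
#'
#' Complete search: minimizes the exact scaled sum of squared residuals
#' first and, among fit-optimal models, the size. The branch-and-bound
#' explores per-target gate subsets in topological order with admissible
#' bounds; on cyclic hypergraphs it falls back to exhaustive search with
#' fixpoint simulation at the leaves, so the result is the global optimum in
#' both cases.
#'
#' @param hg a `hypergraph`.
#' @param dataset a `midas_dataset` (values in `[0, 1]`).
#' @param precision discretization digits (default 2).
#' @param max_steps simulation step cap; default `3 * n_nodes`.
#' @return list with `mse_opt`, `sse_opt` (scaled integer), `n_compared`,
#'   `size_opt` and `witness` (one optimal `logic_model`).
#' @export
find_optimum <- function(hg, dataset, precision = 2, max_steps = NULL) {
  a <- search_args(hg, dataset, precision, max_steps)
  res <- search_cpp(a$enc$N, a$enc$gate_target, a$enc$gate_ptr, a$enc$gate_src,
                    a$enc$gate_sign, a$clamps, a$obs, a$readout_idx, a$pscale,
                    a$max_steps, "optimize", Inf, Inf, Inf)
  list(mse_opt = res$sse_opt / (a$n_compared * a$pscale^2),
       sse_opt = res$sse_opt, n_compared = a$n_compared,
       size_opt = as.integer(res$size_opt),
       witness = logic_model(hg, res$witness))
}

#' Enumerate the complete model family within tolerances
#'
#' Returns every gate subset whose exact MSE is at most
#' `(1 + fit_tolerance) * MSE_opt` and whose size is within the bound —
#' the complete family, not a sample. Models are reported in canonical
#' lexicographic bit-vector order, deduplicated by construction.
#'
#' @inheritParams find_optimum
#' @param config an [enumeration_config()].
#' @return An object of class `model_family`: the model matrix (`$models`,
#'   rows of 0/1 over canonical hyperedge ids), per-model exact scores
#'   (`$sse_scaled`, `$size`, `$mse`), the optimum (`$mse_opt`,
#'   `$size_opt`), `$n_compared`, and the resolved configuration.
#' @export
enumerate_models <- function(hg, dataset, config = enumeration_config(),
                             max_steps = NULL) {
  stopifnot(inherits(config, "enumeration_config"))
  check_backend(config)
  precision <- config$precision
  opt <- find_optimum(hg, dataset, precision, max_steps)
  size_bound <- if (identical(config$size_bound, "optimal")) opt$size_opt
                else config$size_bound
  a <- search_args(hg, dataset, precision, max_steps)
  sse_bound <- (1 + config$fit_tolerance) * opt$sse_opt
  res <- search_cpp(a$enc$N, a$enc$gate_target, a$enc$gate_ptr, a$enc$gate_src,
                    a$enc$gate_sign, a$clamps, a$obs, a$readout_idx, a$pscale,
                    a$max_steps, "enumerate", sse_bound, size_bound,
                    config$max_models)
  models <- res$models
  ord <- do.call(order, as.data.frame(models))
  models <- models[ord, , drop = FALSE]
  colnames(models) <- paste0("g", hg$edges$id)
  structure(list(hypergraph = hg,
                 models = models,
                 sse_scaled = res$sse[ord],
                 size = as.integer(res$size[ord]),
                 mse = res$sse[ord] / (a$n_compared * a$pscale^2),
                 n_compared = a$n_compared,
                 mse_opt = opt$mse_opt, sse_opt = opt$sse_opt,
                 size_opt = opt$size_opt,
                 config = config),
            class = "model_family")
}

#' @export
print.model_family <- function(x, ...) {
  cat(sprintf(paste0("Model family: %d models (tolerance %g%%, size <= %s)\n",
                     "  optimum: MSE = %.6g, size = %d\n"),
              nrow(x$models), 100 * x$config$fit_tolerance,
              if (identical(x$config$size_bound, "optimal")) x$size_opt
              else x$config$size_bound,
              x$mse_opt, x$size_opt))
  invisible(x)
}

#' Number of models in a family
#' @param x a `model_family`.
#' @return Integer count.
#' @export
n_models <- function(x) nrow(x$models)

#' Extract one family member as a logic model
#' @param x a `model_family`.
#' @param i model index (row of `x$models`).
#' @return A `logic_model`.
#' @export
family_model <- function(x, i) logic_model(x$hypergraph, x$models[i, ])

#' Distinct MSE values across a family
#'
#' @param x a `model_family`.
#' @return data frame with ascending `mse`, the exact `sse_scaled` it comes
#'   from, and the `count` of models at that fit; counts sum to the family
#'   size.
#' @export
family_mse_spectrum <- function(x) {
  stopifnot(inherits(x, "model_family"))
  if (!nrow(x$models)) stop("empty family")
  tab <- table(x$sse_scaled)
  sse <- as.numeric(names(tab))
  o <- order(sse)
  data.frame(mse = sse[o] / (x$n_compared * 10^(2 * x$config$precision)),
             sse_scaled = sse[o],
             count = as.integer(tab)[o])
}

#' Write / read a model family as CSV (+ JSON metadata)
#'
#' The CSV holds one row per model: 0/1 columns `g<id>` over canonical
#' hyperedge ids, then `mse` and `size`. `write_family` also writes a
#' `<path>.meta.json` with the optimum, tolerances and counts so the family
#' can be reloaded for analysis.
#'
#' @param x a `model_family`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_family <- function(x, path) {
  stopifnot(inherits(x, "model_family"))
  df <- as.data.frame(x$models)
  df$mse <- x$mse
  df$size <- x$size
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(n_models = nrow(x$models),
               mse_opt = x$mse_opt, sse_opt = x$sse_opt,
               size_opt = x$size_opt, n_compared = x$n_compared,
               precision = x$config$precision,
               fit_tolerance = x$config$fit_tolerance,
               size_bound = x$config$size_bound,
               backend = x$config$backend,
               n_hyperedges = nrow(x$hypergraph$edges))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_family
#' @param hg the `hypergraph` the family was enumerated over.
#' @export
read_family <- function(path, hg) {
  stopifnot(inherits(hg, "hypergraph"))
  df <- utils::read.csv(path, check.names = FALSE)
  gcols <- paste0("g", hg$edges$id)
  if (!all(gcols %in% names(df)))
    stop("family file schema mismatch: missing column ",
         gcols[!gcols %in% names(df)][1])
  for (col in c("mse", "size"))
    if (!col %in% names(df)) stop("family file schema mismatch: missing column ", col)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  models <- as.matrix(df[gcols])
  storage.mode(models) <- "integer"
  precision <- meta$precision %||% 2
  n_compared <- meta$n_compared %||% NA_integer_
  structure(list(hypergraph = hg, models = models,
                 sse_scaled = if (!is.na(n_compared))
                   round(df$mse * n_compared * 10^(2 * precision)) else NA,
                 size = as.integer(df$size), mse = df$mse,
                 n_compared = n_compared,
                 mse_opt = meta$mse_opt %||% min(df$mse),
                 sse_opt = meta$sse_opt %||% NA,
                 size_opt = meta$size_opt %||% NA_integer_,
                 config = enumeration_config(
                   fit_tolerance = meta$fit_tolerance %||% 0,
                   size_bound = if (identical(meta$size_bound, "optimal"))
                     "optimal" else meta$size_bound %||% "optimal",
                   precision = precision)),
            class = "model_family")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
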