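#' Read a signed network from a Cytoscape SIF file
#'
#' Each line holds `source relation target`, whitespace- or tab-separated.
#' Accepted relation tokens: `1` / `activates` (sign +1) and `-1` /
#' `inhibits` (sign -1). Node roles are empty; set them afterwards from the
#' MIDAS header or a configuration (see [set_roles()]).
#'
#' @param path SIF file path.
#' @return A [pkn()] with empty roles.
#' @export
read_sif <- function(path) {
  if (!file.exists(path)) stop("SIF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) stop("SIF file is empty: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  n <- lengths(fields)
  isolated <- unlist(fields[n == 1])       # single-field line: isolated node
  fields <- fields[n != 1]
  lineno <- lineno[n != 1]
  n <- n[n != 1]
  if (any(n < 3))
    stop(sprintf("malformed SIF line %d: fewer than 3 fields", lineno[which(n < 3)[1]]))
  if (!length(fields))
    return(pkn(data.frame(source = character(), sign = integer(),
                          target = character()), nodes = isolated))
  rel <- vapply(fields, `[[`, "", 2L)
  sign <- ifelse(rel %in% c("1", "activates"), 1L,
                 ifelse(rel %in% c("-1", "inhibits"), -1L, NA_integer_))
  if (anyNA(sign))
    stop(sprintf("unknown relation token '%s' on SIF line %d",
                 rel[which(is.na(sign))[1]], lineno[which(is.na(sign))[1]]))
  # SIF allows multiple targets per line: source rel t1 t2 ...
  src <- rep(vapply(fields, `[[`, "", 1L), n - 2L)
  sgn <- rep(sign, n - 2L)
  tgt <- unlist(lapply(fields, function(f) f[-(1:2)]), use.names = FALSE)
  pkn(data.frame(source = src, sign = sgn, target = tgt,
                 stringsAsFactors = FALSE), nodes = isolated)
}

#' Write a network to SIF
#'
#' @param x a `pkn`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(x, path) {
  stopifnot(inherits(x, "pkn"))
  isolated <- setdiff(x$nodes, c(x$edges$source, x$edges$target))
  writeLines(c(paste(x$edges$source, x$edges$sign, x$edges$target, sep = "\t"),
               isolated), path)
  invisible(path)
}
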