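# File formats: TSV matrices, regulatory-network edge lists, GMT pathway
# sets, reaction tables, and YAML simulation configs.

#' Write a numeric matrix as TSV
#'
#' Header row plus a first `id` column; values are written with 17
#' significant digits so that write-then-read reproduces doubles exactly.
#'
#' @param m matrix with dimnames.
#' @param path output file.
#' @export
write_matrix_tsv <- function(m, path) {
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  header <- paste(c("id", colnames(m)), collapse = "\t")
  body <- if (nrow(m) == 0) character(0) else
    paste(ids, apply(m, 1, function(r)
      paste(sprintf("%.17g", r), collapse = "\t")),
      sep = if (ncol(m) > 0) "\t" else "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a TSV matrix written by [write_matrix_tsv()]
#'
#' @param path input file.
#' @return numeric matrix with row and column names.
#' @export
read_matrix_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (anyDuplicated(d[[1]]))
    stop("read_matrix_tsv: duplicate ids in ", path)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(d[[1]])
  m
}

#' Read a TRRUST-style regulatory network edge list
#'
#' Three tab-separated columns: TR, target gene, mode (Activation,
#' Repression or Unknown). Duplicate (TR, gene) pairs are collapsed;
#' conflicting modes become Unknown with a warning.
#'
#' @param path input TSV (no header).
#' @return data.frame with `tr`, `target`, `mode`.
#' @export
read_regulatory_network <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 3) stop("read_regulatory_network: need 3 columns")
  d <- d[, 1:3]
  names(d) <- c("tr", "target", "mode")
  bad <- !d$mode %in% c("Activation", "Repression", "Unknown")
  if (any(bad))
    stop("read_regulatory_network: malformed mode token(s): ",
         paste(unique(d$mode[bad]), collapse = ", "))
  if (any(!nzchar(d$tr)) || any(!nzchar(d$target)))
    stop("read_regulatory_network: empty ids")
  key <- paste(d$tr, d$target, sep = "\r")
  if (anyDuplicated(key)) {
    modes <- tapply(d$mode, key, function(m) {
      u <- unique(m)
      if (length(u) > 1) "conflict" else u
    })
    d <- d[!duplicated(key), ]
    km <- modes[paste(d$tr, d$target, sep = "\r")]
    if (any(km == "conflict")) {
      warning("read_regulatory_network: conflicting duplicate modes set ",
              "to Unknown")
      d$mode[km == "conflict"] <- "Unknown"
    }
  }
  rownames(d) <- NULL
  d
}

#' Write a regulatory network edge list
#' @param network data.frame with `tr`, `target`, `mode`.
#' @param path output TSV.
#' @export
write_regulatory_network <- function(network, path) {
  utils::write.table(network[, c("tr", "target", "mode")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read pathway sets from a GMT file
#' @param path GMT file (name, description, members, tab-separated).
#' @return named list of member id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[`, "", 1))
}

#' Write pathway sets to a GMT file
#' @param sets named list of member id vectors.
#' @param path output file.
#' @param description description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  writeLines(vapply(names(sets), function(n)
    paste(c(n, description, sets[[n]]), collapse = "\t"), ""), path)
  invisible(path)
}

#' Read a stoichiometric reaction table
#'
#' TSV with header: reaction_id, gene_ids, substrates, products
#' (`;`-separated id lists).
#'
#' @param path input TSV.
#' @return data.frame suitable for [metabolic_graph()].
#' @export
read_reaction_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  need <- c("reaction_id", "gene_ids", "substrates", "products")
  if (!all(need %in% names(d)))
    stop("read_reaction_table: missing column(s) ",
         paste(setdiff(need, names(d)), collapse = ", "))
  d[, need]
}

#' Write a simulation config as YAML
#' @param config a [sim_config()].
#' @param path output file.
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a simulation config from YAML
#'
#' Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return a validated [sim_config()].
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("read_sim_config: unknown key(s): ",
         paste(unknown, collapse = ", "))
  do.call(sim_config, vals)
}
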