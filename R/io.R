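#' Read aligned sequences from FASTA
#'
#' Tolerates wrapped lines and CRLF endings; rejects duplicate ids and
#' empty records.
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_pcg("no such file: ", path)
  lines <- sub("\r$", "", readLines(path))
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1L]) stop_pcg(path, ": not a FASTA file")
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  if (anyDuplicated(ids)) {
    stop_pcg(path, ": duplicate sequence id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, "", collapse = "")
  if (length(seqs) != length(ids) || any(!nzchar(seqs))) {
    stop_pcg(path, ": empty sequence record")
  }
  setNames(toupper(unname(seqs)), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line-wrap width (default 70).
#' @export
write_fasta <- function(seqs, path, width = 70) {
  if (is.null(names(seqs))) stop_pcg("sequences must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a rooted tree with branch lengths from newick
#'
#' @param path newick file.
#' @return phylo object; errors if branch lengths are missing or tip labels
#'   duplicated.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop_pcg("no such file: ", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop_pcg(path, ": not a newick tree")
  if (is.null(tr$edge.length)) stop_pcg(path, ": tree has no branch lengths")
  if (anyDuplicated(tr$tip.label)) {
    stop_pcg(path, ": duplicate tip label(s): ",
             paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                   collapse = ", "))
  }
  tr
}

#' Write a tree to newick
#'
#' @param tree phylo object.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a scenario dataset to a directory
#'
#' Emits `table.tsv` (taxa x samples counts), `sequences.fasta`,
#' `tree.nwk`, `traits.tsv`, and `truth.json`.
#'
#' @param dataset a `pcg_dataset` from [generate_scenario()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!inherits(dataset, "pcg_dataset")) stop_pcg("not a pcg_dataset")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_abundance_tsv(dataset$table, file.path(dir, "table.tsv"))
  write_fasta(dataset$sequences, file.path(dir, "sequences.fasta"))
  write_newick(dataset$tree, file.path(dir, "tree.nwk"))
  write.table(dataset$traits, file.path(dir, "traits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' Read a pipeline run configuration from YAML
#'
#' Unknown keys are rejected; numeric parameters are range-checked when the
#' pipeline consumes them.
#'
#' @param path YAML file.
#' @return named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  allowed <- c("metric", "k_max", "n_perm", "alpha", "ci", "n_sim",
               "thresholds", "min_count", "n_null", "seed", "escalate")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop_pcg(path, ": unknown configuration key(s): ",
             paste(unknown, collapse = ", "))
  }
  cfg
}
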