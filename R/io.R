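# Readers and writers for the standard interchange formats: Newick
# trees (ape), FASTA (ape), tab-separated trait and feature tables
# (data.table; transparently gzipped), BIOM feature tables (biomformat),
# and JSON run manifests (jsonlite). Every writer's output is readable
# by its paired reader.

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  setNames(toupper(vapply(as.character(dna), paste, "", collapse = "")),
           names(dna))
}

#' Write a named character vector of sequences as FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) .fail("sequences must be named")
  dna <- ape::as.DNAbin(lapply(seqs, function(s)
    strsplit(tolower(s), "", fixed = TRUE)[[1L]]))
  ape::write.FASTA(dna, path)
  invisible(path)
}

#' Read a Newick tree (branch lengths required)
#' @param path Newick file.
#' @return a `phylo`.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) .fail("could not parse Newick file %s", path)
  if (is.null(tree$edge.length))
    .fail("tree %s has no branch lengths (required for NSTI)", path)
  tree
}

#' Write a tree as Newick with full branch-length precision
#' @param tree a `phylo`.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

# gz-transparent TSV reader (fread needs R.utils for .gz, which may be
# absent; base connections handle gzip natively)
#' @noRd
.read_tsv <- function(path) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    utils::read.delim(con, header = TRUE, sep = "\t",
                      check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    data.table::fread(path, header = TRUE, sep = "\t",
                      data.table = FALSE)
  }
}

#' Read a trait table from TSV (optionally gzipped)
#'
#' First column = genome/query id, header row = trait ids.
#'
#' @param path TSV(.gz) file.
#' @param framework framework id to stamp on the table.
#' @return a [trait_table()].
#' @export
read_trait_table <- function(path, framework) {
  dt <- .read_tsv(path)
  ids <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- ids
  trait_table(m, framework)
}

#' Write a trait table as TSV (gzipped when the path ends in .gz)
#' @param table a [trait_table()] or named numeric matrix.
#' @param path output file.
#' @param id_col name of the id column (default "genome_id").
#' @export
write_trait_table <- function(table, path, id_col = "genome_id") {
  m <- unclass(table)
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read a feature table (TSV or BIOM)
#'
#' TSV: first column ASV id, header = sample ids. Files ending in
#' `.biom` are read with the biomformat package. IDs are preserved
#' verbatim; counts are validated non-negative and ids unique.
#'
#' @param path input file.
#' @return ASV x sample numeric matrix.
#' @export
read_feature_table <- function(path) {
  if (grepl("\\.biom$", path)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      .fail("reading BIOM requires the biomformat package")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
  } else {
    dt <- .read_tsv(path)
    m <- as.matrix(dt[, -1L, drop = FALSE])
    mode(m) <- "numeric"
    rownames(m) <- as.character(dt[[1L]])
  }
  check_feature_table(m)
  m
}

#' Write a feature table (TSV, gz-aware, or BIOM by extension)
#' @param table ASV x sample matrix.
#' @param path output file; `.biom` selects BIOM output.
#' @export
write_feature_table <- function(table, path) {
  check_feature_table(table)
  if (grepl("\\.biom$", path)) {
    if (!requireNamespace("biomformat", quietly = TRUE))
      .fail("writing BIOM requires the biomformat package")
    biomformat::write_biom(biomformat::make_biom(table), path)
  } else {
    write_trait_table(table, path, id_col = "asv_id")
  }
  invisible(path)
}

#' Write a reference database to a directory of plain-text files
#'
#' Per domain: `tree_<domain>.nwk`, `ssu_<domain>.fna`, and one
#' `traits_<domain>_<framework>.tsv.gz` per framework; plus
#' `manifest.json` (version, thresholds, per-stage counts; no
#' timestamps, so identical builds are byte-identical).
#'
#' @param db a `ref_db`.
#' @param dir output directory (created).
#' @export
write_ref_db <- function(db, dir) {
  stopifnot(inherits(db, "ref_db"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in names(db$domains)) {
    dd <- db$domains[[d]]
    write_newick(dd$tree, file.path(dir, sprintf("tree_%s.nwk", d)))
    write_fasta(dd$ssu, file.path(dir, sprintf("ssu_%s.fna", d)))
    for (f in names(dd$traits))
      write_trait_table(dd$traits[[f]],
                        file.path(dir, sprintf("traits_%s_%s.tsv.gz",
                                               d, f)))
  }
  jsonlite::write_json(db$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a reference database written by [write_ref_db()]
#' @param dir database directory.
#' @return a `ref_db`.
#' @export
read_ref_db <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  domains <- list()
  for (d in c("bacteria", "archaea")) {
    tf <- file.path(dir, sprintf("tree_%s.nwk", d))
    if (!file.exists(tf)) next
    traits <- list()
    for (f in manifest$frameworks) {
      p <- file.path(dir, sprintf("traits_%s_%s.tsv.gz", d, f))
      if (file.exists(p)) traits[[f]] <- read_trait_table(p, f)
    }
    domains[[d]] <- list(tree = read_newick(tf),
                         traits = traits,
                         ssu = read_fasta(file.path(dir,
                                          sprintf("ssu_%s.fna", d))))
  }
  structure(list(domains = domains, manifest = manifest),
            class = "ref_db")
}

#' Write a placement table (mirrors the per-query NSTI output convention)
#' @param placements result of [place_queries()].
#' @param path output TSV.
#' @export
write_placements <- function(placements, path) {
  pls <- attr(placements, "placements")
  extra <- do.call(rbind, lapply(placements$query_id, function(q) {
    pl <- pls[[q]]
    if (is.null(pl)) data.frame(nearest_tip = NA_character_,
                                pendant = NA_real_)
    else data.frame(nearest_tip = pl$nearest_tip, pendant = pl$pendant)
  }))
  df <- cbind(as.data.frame(placements), extra)
  data.table::fwrite(df, path, sep = "\t", na = "NA")
  invisible(path)
}

#' Read a placement table and rebuild placement objects against a database
#' @param path TSV from [write_placements()].
#' @param db the `ref_db` the placements refer to.
#' @return a placements data.frame as from [place_queries()].
#' @export
read_placements <- function(path, db) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE,
                          na.strings = "NA")
  pls <- setNames(vector("list", nrow(df)), df$query_id)
  for (i in seq_len(nrow(df))) {
    if (is.na(df$chosen_domain[i])) next
    tree <- db$domains[[df$chosen_domain[i]]]$tree
    tip <- match(df$nearest_tip[i], tree$tip.label)
    if (is.na(tip)) .fail("tip %s not in %s tree", df$nearest_tip[i],
                          df$chosen_domain[i])
    row <- which(tree$edge[, 2L] == tip)
    pls[[df$query_id[i]]] <- structure(
      list(query_id = df$query_id[i], status = "ok",
           nearest_tip = df$nearest_tip[i],
           edge = c(parent = tree$edge[row, 1L], child = tip),
           distal = 0, pendant = df$pendant[i],
           n_informative = NA_integer_),
      class = "placement")
  }
  out <- df[, c("query_id", "nsti_bacteria", "nsti_archaea",
                "chosen_domain", "chosen_nsti",
                "predicted_16S_copies")]
  attr(out, "placements") <- pls
  out
}

#' Serialise a run configuration into an output directory
#'
#' Written to every output directory as `run_config.json` for
#' reproducibility. Deliberately contains no timestamps so repeated runs
#' are byte-identical.
#'
#' @param config named list of parameters.
#' @param outdir output directory.
#' @export
write_run_config <- function(config, outdir) {
  jsonlite::write_json(config, file.path(outdir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
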