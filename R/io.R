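# On-disk universe formats:
#   smd.csv   id,smiles
#   biod.fasta  (header = id, 60-column wrap)
#   ssi.tsv / bbi.tsv / spi.tsv / bpi.tsv   from<TAB>to with header
#   sbi.csv   drug_a,drug_b,mechanism,action
#   counts.json sidecar with entity/edge/positive counts

#' Load a drug universe from its on-disk representation
#'
#' @param smiles_path CSV with columns `id`, `smiles` (one SMD per row).
#' @param fasta_path FASTA of BioD amino-acid sequences; record id = drug id.
#' @param edge_paths named character vector/list with elements `SSI`, `BBI`,
#'   `SPI`, `BPI`, each a two-column (`from`, `to`) TSV with header.
#' @param sbi_path CSV with columns `drug_a`, `drug_b`, `mechanism`,
#'   `action`.
#' @param min_count rare-event threshold for the event catalog.
#' @return A validated [drug_universe()]. The protein set is the sorted
#'   union of partner nodes observed in the SPI and BPI files.
#' @export
load_universe <- function(smiles_path, fasta_path, edge_paths, sbi_path,
                          min_count = 10) {
  for (p in c(smiles_path, fasta_path, unlist(edge_paths), sbi_path))
    if (!file.exists(p)) stopf("input file not found: %s", p)

  smd <- read_checked_csv(smiles_path, c("id", "smiles"))
  aa <- tryCatch(Biostrings::readAAStringSet(fasta_path),
                 error = function(e) stopf("malformed FASTA '%s': %s",
                                           fasta_path, conditionMessage(e)))
  biod <- data.frame(id = sub("\\s.*$", "", names(aa)),
                     kind = "BioD",
                     structure = as.character(aa),
                     stringsAsFactors = FALSE)
  drugs <- rbind(data.frame(id = smd$id, kind = "SMD", structure = smd$smiles,
                            stringsAsFactors = FALSE),
                 biod)

  edges <- lapply(.network_names, function(net) {
    p <- edge_paths[[net]]
    if (is.null(p)) stopf("edge_paths is missing network '%s'", net)
    e <- utils::read.delim(p, header = TRUE, colClasses = "character")
    if (!all(c("from", "to") %in% names(e)))
      stopf("edge file '%s' must have header columns 'from' and 'to'", p)
    e[c("from", "to")]
  })
  names(edges) <- .network_names

  proteins <- sort(unique(c(edges$SPI$to, edges$BPI$to)))
  sbi <- read_checked_csv(sbi_path, c("drug_a", "drug_b", "mechanism", "action"))
  uni <- drug_universe(drugs, proteins, edges, sbi, min_count = min_count)
  sbi_log(sprintf("loaded universe: %d SMD, %d BioD, %d proteins, %d positives",
                  length(smd_ids(uni)), length(biod_ids(uni)),
                  length(uni$proteins), nrow(uni$sbi)))
  uni
}

read_checked_csv <- function(path, columns) {
  x <- tryCatch(utils::read.csv(path, colClasses = "character"),
                error = function(e) stopf("malformed CSV '%s': %s", path,
                                          conditionMessage(e)))
  missing <- setdiff(columns, names(x))
  if (length(missing))
    stopf("'%s' is missing column(s): %s", path, paste(missing, collapse = ", "))
  bad <- which(!stats::complete.cases(x[columns]) |
                 rowSums(x[columns] == "") > 0)
  if (length(bad))
    stopf("'%s' has empty/missing fields at data line(s): %s", path,
          paste(utils::head(bad, 5), collapse = ", "))
  x[columns]
}

#' Write a drug universe in the formats read by [load_universe()]
#'
#' Files written: `smd.csv`, `biod.fasta` (wrapped at 60 columns),
#' `ssi.tsv`/`bbi.tsv`/`spi.tsv`/`bpi.tsv`, `sbi.csv`, and a `counts.json`
#' sidecar of entity, edge and positive-pair counts.
#'
#' @param universe a `drug_universe`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_universe <- function(universe, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  smd <- universe$drugs[universe$drugs$kind == "SMD", ]
  biod <- universe$drugs[universe$drugs$kind == "BioD", ]
  paths <- c(
    smd = file.path(dir, "smd.csv"), biod = file.path(dir, "biod.fasta"),
    SSI = file.path(dir, "ssi.tsv"), BBI = file.path(dir, "bbi.tsv"),
    SPI = file.path(dir, "spi.tsv"), BPI = file.path(dir, "bpi.tsv"),
    sbi = file.path(dir, "sbi.csv"), counts = file.path(dir, "counts.json"))

  utils::write.csv(data.frame(id = smd$id, smiles = smd$structure),
                   paths[["smd"]], row.names = FALSE, quote = FALSE)
  seqs <- Biostrings::AAStringSet(stats::setNames(biod$structure, biod$id))
  Biostrings::writeXStringSet(seqs, paths[["biod"]], width = 60)
  for (net in .network_names)
    utils::write.table(universe$edges[[net]], paths[[net]], sep = "\t",
                       row.names = FALSE, quote = FALSE)
  utils::write.csv(universe$sbi, paths[["sbi"]], row.names = FALSE, quote = FALSE)

  counts <- list(SMD = nrow(smd), BioD = nrow(biod),
                 Protein = length(universe$proteins),
                 SSI = nrow(universe$edges$SSI), BBI = nrow(universe$edges$BBI),
                 SPI = nrow(universe$edges$SPI), BPI = nrow(universe$edges$BPI),
                 SBI = nrow(universe$sbi))
  jsonlite::write_json(counts, paths[["counts"]], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
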