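#' Read and write the standard file interfaces
#'
#' Pedigree CSV (`id,sire,dam,sex,generation`; 0 = unknown parent, ids in
#' birth order), phenotype CSV (`id,phenotype`), and the BLUPF90-style SNP
#' file: one line per animal, the id, a run of whitespace, then the
#' unbroken genotype string of 0/1/2 codes (5 would denote a missing call;
#' the simulator never writes it).
#'
#' @param ped,phen,codes objects to write.
#' @param file path.
#' @name io
NULL

#' @rdname io
#' @export
write_pedigree <- function(ped, file) {
  utils::write.csv(ped[, c("id", "sire", "dam", "sex", "generation")],
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname io
#' @export
read_pedigree <- function(file) {
  ped <- utils::read.csv(file, stringsAsFactors = FALSE)
  check_pedigree(ped)
  ped
}

#' @rdname io
#' @export
write_phenotypes <- function(phen, file) {
  utils::write.csv(phen[, c("id", "phenotype")], file,
                   row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname io
#' @export
read_phenotypes <- function(file) utils::read.csv(file)

#' @rdname io
#' @export
write_snp_file <- function(codes, file) {
  ids <- rownames(codes)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(codes)))
  strings <- apply(codes, 1L, paste0, collapse = "")
  writeLines(sprintf("%s %s", ids, strings), file)
  invisible(file)
}

#' @rdname io
#' @export
read_snp_file <- function(file) {
  lines <- readLines(file)
  parts <- regmatches(lines, regexpr("^\\S+", lines))
  geno_str <- sub("^\\S+\\s+", "", lines)
  n_loci <- nchar(geno_str[1])
  if (any(nchar(geno_str) != n_loci)) stop("ragged genotype strings")
  codes <- matrix(as.integer(unlist(strsplit(geno_str, "", fixed = TRUE))),
                  nrow = length(lines), ncol = n_loci, byrow = TRUE)
  rownames(codes) <- parts
  codes
}

#' Write or read a simulation configuration
#'
#' Human-readable key-value (YAML) rendering of a [sim_config()].
#'
#' @param config a `sim_config`.
#' @param file path.
#' @export
write_config <- function(config, file) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  x <- yaml::read_yaml(file)
  do.call(sim_config, x[names(x) %in% names(formals(sim_config))])
}

#' Export a simulated population to disk
#'
#' Writes `pedigree.csv`, `pheno.csv`, `geno_train.snp` and `geno_val.snp`
#' (training and validation SNP-panel genotypes) under `dir`. All formats
#' round-trip losslessly through the matching readers.
#'
#' @param pop a `population`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
export_population <- function(pop, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- c(pedigree = file.path(dir, "pedigree.csv"),
         pheno = file.path(dir, "pheno.csv"),
         train = file.path(dir, "geno_train.snp"),
         val = file.path(dir, "geno_val.snp"))
  write_pedigree(pop$ped, f["pedigree"])
  write_phenotypes(data.frame(id = pop$ped$id, phenotype = pop$phenotype),
                   f["pheno"])
  write_snp_file(pop_genotypes(pop, training_ids(pop)), f["train"])
  write_snp_file(pop_genotypes(pop, validation_ids(pop)), f["val"])
  invisible(f)
}
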