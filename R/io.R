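# File formats: PLINK .raw/.map additive dialect, plain TSV matrix + map,
# phenotype TSV, and TSV + JSON manifest result writing.

#' Genotype matrix container
#'
#' Couples a sires-by-SNPs matrix of additive codes (0/1/2 copies of the B
#' allele, `NA` for missing) with its SNP map and per-sire call rates.
#'
#' @param codes numeric matrix, sires in rows, SNPs in columns.
#' @param map data.frame with columns `snp_id`, `chr` (positive integer) and
#'   `bp` (1-based physical position); one row per column of `codes`.
#' @param sire_ids character vector of row identifiers.
#' @return object of class `geno_matrix`: list with `codes` (with dimnames),
#'   `map`, `sire_ids`, `call_rate`.
#' @export
geno_matrix <- function(codes, map, sire_ids = rownames(codes)) {
  codes <- as.matrix(codes)
  if (is.null(sire_ids)) sire_ids <- sprintf("sire%04d", seq_len(nrow(codes)))
  map <- as.data.frame(map)
  need <- c("snp_id", "chr", "bp")
  if (!all(need %in% names(map)))
    stop("map must have columns snp_id, chr, bp")
  if (nrow(map) == 0L) stop("empty map")
  if (ncol(codes) != nrow(map))
    stop("dimension mismatch: ", ncol(codes), " genotype columns vs ",
         nrow(map), " map rows")
  if (anyDuplicated(map$snp_id))
    stop("duplicate SNP id: ", map$snp_id[duplicated(map$snp_id)][1])
  bad <- !(codes %in% c(0, 1, 2) | is.na(codes))
  if (any(bad))
    stop("non-{0,1,2,NA} genotype code found (first offending value: ",
         codes[which(bad)[1]], ")")
  storage.mode(codes) <- "double"
  dimnames(codes) <- list(sire_ids, map$snp_id)
  structure(list(codes = codes, map = map, sire_ids = sire_ids,
                 call_rate = rowMeans(!is.na(codes))),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", length(x$sire_ids), "sires x", nrow(x$map), "SNPs on",
      length(unique(x$map$chr)), "chromosome(s);",
      sprintf("min call rate %.3f\n", min(x$call_rate)))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$codes)

#' Read sire genotypes
#'
#' Two dialects are supported. `"tsv"`: a matrix file whose first column is
#' the sire id and remaining columns are SNPs (header = SNP ids), plus a map
#' TSV with header `snp_id`, `chr`, `bp`. `"plink_raw"`: a PLINK `--recode A`
#' additive file (`FID IID PAT MAT SEX PHENOTYPE SNP1_A ...`) plus a
#' headerless PLINK `.map` (`chr snp_id cm bp`).
#'
#' @param path path to the genotype matrix (`.raw` or TSV).
#' @param map_path path to the map file.
#' @param dialect `"tsv"` or `"plink_raw"`.
#' @return a [geno_matrix()]. Missing entries stay `NA`; nothing is imputed.
#' @export
read_genotypes <- function(path, map_path, dialect = c("tsv", "plink_raw")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (!file.exists(map_path)) stop("map file not found: ", map_path)
  if (dialect == "tsv") {
    tab <- read.table(path, header = TRUE, sep = "\t",
                      check.names = FALSE, stringsAsFactors = FALSE)
    sire_ids <- as.character(tab[[1]])
    codes <- as.matrix(tab[, -1, drop = FALSE])
    map <- read.table(map_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else {
    tab <- read.table(path, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE)
    fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(fixed %in% names(tab)[1:6]))
      stop("not a PLINK .raw file: expected header ", paste(fixed, collapse = " "))
    sire_ids <- as.character(tab$IID)
    codes <- as.matrix(tab[, -(1:6), drop = FALSE])
    map <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                      col.names = c("chr", "snp_id", "cm", "bp"))
    map <- map[, c("snp_id", "chr", "bp")]
    # strip the _<allele> suffix PLINK appends to SNP names, but only if
    # that recovers the map's identifiers
    stripped <- sub("_[ACGT12]$", "", colnames(codes))
    if (identical(stripped, as.character(map$snp_id)))
      colnames(codes) <- stripped
  }
  if (nrow(map) == 0L) stop("empty map")
  if (anyDuplicated(map$snp_id))
    stop("duplicate SNP id: ", map$snp_id[duplicated(map$snp_id)][1])
  if (!identical(colnames(codes), as.character(map$snp_id)))
    if (ncol(codes) != nrow(map))
      stop("dimension mismatch: ", ncol(codes), " genotype columns vs ",
           nrow(map), " map rows")
    else stop("SNP ids in matrix and map disagree")
  geno_matrix(codes, map, sire_ids)
}

#' Write sire genotypes
#'
#' Inverse of [read_genotypes()] for both dialects.
#'
#' @param geno a [geno_matrix()].
#' @param path,map_path output paths.
#' @param dialect `"tsv"` or `"plink_raw"`.
#' @return invisibly, the two paths.
#' @export
write_genotypes <- function(geno, path, map_path,
                            dialect = c("tsv", "plink_raw")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    tab <- data.frame(sire_id = geno$sire_ids, geno$codes,
                      check.names = FALSE, stringsAsFactors = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(geno$map, map_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    tab <- data.frame(FID = geno$sire_ids, IID = geno$sire_ids,
                      PAT = 0L, MAT = 0L, SEX = 0L, PHENOTYPE = -9,
                      geno$codes, check.names = FALSE)
    colnames(tab)[-(1:6)] <- paste0(geno$map$snp_id, "_A")
    write.table(tab, path, sep = " ", quote = FALSE, row.names = FALSE)
    write.table(data.frame(geno$map$chr, geno$map$snp_id, 0, geno$map$bp),
                map_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(c(path, map_path))
}

#' Read progeny phenotypes
#'
#' Reads a TSV with header columns `animal_id`, `sire_id`, `cg`, `sex`,
#' `age`, `y`. Rows with missing trait values are dropped with a message
#' giving the count.
#'
#' @param path path to the phenotype TSV.
#' @return data.frame of typed records.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = "character", na.strings = c("NA", ""))
  need <- c("animal_id", "sire_id", "cg", "sex", "age", "y")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  to_num <- function(x, name) {
    out <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(out)
    if (any(bad))
      stop("non-numeric ", name, " value: '", x[bad][1], "'")
    out
  }
  tab$age <- to_num(tab$age, "age")
  tab$y <- to_num(tab$y, "y")
  if (any(tab$age <= 0, na.rm = TRUE)) stop("age must be positive")
  drop <- is.na(tab$y)
  if (any(drop))
    message("read_phenotypes: dropped ", sum(drop),
            " record(s) with missing trait value")
  tab[!drop, need, drop = FALSE]
}

#' Write progeny phenotypes
#'
#' @param pheno phenotype data.frame.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_phenotypes <- function(pheno, path) {
  write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write result tables with a JSON manifest
#'
#' Writes each named table as a TSV with a fixed column order (as given) and
#' a `manifest.json` recording file names, row counts, the seed, a hash of
#' the configuration, and package/R versions, so a result directory is
#' self-describing.
#'
#' @param tables named list of data.frames (may be empty).
#' @param out_dir output directory; created if absent.
#' @param seed optional integer recorded in the manifest.
#' @param config optional list recorded (hashed) in the manifest.
#' @return invisibly, the manifest as a list.
#' @export
write_results <- function(tables, out_dir, seed = NULL, config = NULL) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  stopifnot(is.list(tables))
  if (length(tables) && is.null(names(tables)))
    stop("tables must be named")
  files <- list()
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    tab <- as.data.frame(tables[[nm]])
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], function(x) signif(x, 12))
    write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[nm]] <- list(file = basename(f), n_rows = nrow(tab))
  }
  cfg_hash <- if (is.null(config)) NULL else {
    tf <- tempfile(); on.exit(unlink(tf), add = TRUE)
    writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                                force = TRUE), tf)
    unname(tools::md5sum(tf))
  }
  manifest <- list(
    files = files,
    seed = seed,
    config_md5 = cfg_hash,
    versions = list(hetvar = as.character(packageVersion("hetvar")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}
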