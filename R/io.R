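#' Write a simulated dataset as PLINK-style .ped/.map plus TSV truth files
#'
#' \code{.map}: chromosome, marker id, cM, bp.  \code{.ped}: family (the
#' grandsire id), individual, sire, dam (0), sex (1), phenotype (0), then two
#' allele columns per marker coded 1/2.  Alongside, a pedigree TSV and a
#' truth TSV (one crossover per row: sire, son, chrom, cM, bp) are written.
#'
#' @param sim a \code{\link{simulate_dataset}} result.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return invisibly, the paths written.
#' @export
write_plink <- function(sim, dir, prefix = "sim") {
  stopifnot(inherits(sim, "recomb_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  map_path <- file.path(dir, paste0(prefix, ".map"))
  ped_path <- file.path(dir, paste0(prefix, ".ped"))
  utils::write.table(sim$map[, c("chrom", "id", "cM", "bp")], map_path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  ped <- sim$pedigree
  fam <- family_of(ped)
  G <- do.call(cbind, sim$geno)
  al <- matrix("", nrow(G), 2L * ncol(G))
  al[, seq(1, 2 * ncol(G), 2)] <- ifelse(G >= 1L, "2", "1")
  al[, seq(2, 2 * ncol(G), 2)] <- ifelse(G == 2L, "2", "1")
  lead <- cbind(fam[ped$id], ped$id, ifelse(is.na(ped$sire), "0", ped$sire),
                "0", "1", "0")
  utils::write.table(cbind(lead, al[match(ped$id, rownames(G)), , drop = FALSE]),
                     ped_path, sep = " ", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  ped_tsv <- file.path(dir, paste0(prefix, "_pedigree.tsv"))
  utils::write.table(ped, ped_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  truth_tsv <- file.path(dir, paste0(prefix, "_true_co.tsv"))
  utils::write.table(sim$truth$crossovers, truth_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(map = map_path, ped = ped_path, pedigree = ped_tsv,
              truth = truth_tsv))
}

family_of <- function(ped) {
  fam <- ped$id
  names(fam) <- ped$id
  sire <- stats::setNames(ped$sire, ped$id)
  for (i in seq_len(nrow(ped))) {
    id <- ped$id[i]
    while (!is.na(sire[[fam[[id]]]])) fam[[id]] <- sire[[fam[[id]]]]
  }
  fam
}

#' Read PLINK-style .ped/.map back into the package's genotype structures
#'
#' @param ped_path,map_path file paths as written by \code{\link{write_plink}}.
#' @return list \code{geno} (per-chromosome 0/1/2 matrices), \code{map},
#'   \code{pedigree} (from the .ped columns: id and sire).
#' @export
read_plink <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, sep = "\t",
                           col.names = c("chrom", "id", "cM", "bp"))
  raw <- utils::read.table(ped_path, sep = " ", colClasses = "character")
  ids <- raw[[2]]
  sire <- ifelse(raw[[3]] == "0", NA_character_, raw[[3]])
  al <- as.matrix(raw[, -(1:6)])
  M <- ncol(al) / 2
  G <- (al[, seq(1, 2 * M, 2)] == "2") + (al[, seq(2, 2 * M, 2)] == "2")
  rownames(G) <- ids
  geno <- lapply(sort(unique(map$chrom)), function(ci) {
    g <- G[, map$chrom == ci, drop = FALSE]
    storage.mode(g) <- "integer"
    g
  })
  gen <- ifelse(is.na(sire), "GI", ifelse(sire %in% ids[is.na(sire)], "GII", "GIII"))
  list(geno = geno, map = map,
       pedigree = data.frame(id = ids, gen = gen, sire = sire,
                             stringsAsFactors = FALSE))
}

#' Write crossover events as a BED-like TSV
#'
#' Columns: chrom, interval start, interval end, sire, son.
#'
#' @param events crossover data.frame.
#' @param path output file.
#' @export
write_co_tsv <- function(events, path) {
  utils::write.table(events[, c("chrom", "left_bp", "right_bp", "sire", "son")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write window rates as BED (name = flag, score = z)
#'
#' @param rates a \code{\link{normalize_rr}} result.
#' @param path output file.
#' @export
write_windows_bed <- function(rates, path) {
  bed <- data.frame(chrom = rates$chrom, start = rates$start - 1L,
                    end = rates$end, name = rates$flag,
                    score = round(rates$z, 3))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
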