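#' Read a genome assembly from FASTA
#'
#' Reads a (possibly gzip-compressed) multi-record FASTA file into an
#' assembly object. Sequences are uppercased; IUPAC ambiguity codes other
#' than `N` are replaced by `N` (a message reports how many); contig ids are
#' the first whitespace-delimited token of each header. Contig order is
#' preserved from file order and is the tie-breaking order for all
#' deterministic scans downstream.
#'
#' @param path path to a FASTA file (`.gz` accepted).
#' @param label assembly label; defaults to the file name without extension.
#' @return an object of class `ssr_assembly`: a list with elements `label`
#'   (character) and `seq` (named character vector of contig sequences over
#'   `A`,`C`,`G`,`T`,`N`).
#' @export
read_assembly <- function(path, label = NULL) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  if (is.null(label)) {
    label <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path))
  }
  dss <- Biostrings::readDNAStringSet(path)
  if (length(dss) == 0L) abort(paste0("no FASTA records in ", path))
  seqs <- toupper(as.character(dss))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (any(nchar(seqs) == 0L)) {
    abort(paste0("empty sequence record(s) in ", path, ": ",
                 paste(names(seqs)[nchar(seqs) == 0L], collapse = ", ")))
  }
  if (anyDuplicated(names(seqs))) {
    abort(paste0("duplicate contig ids in ", path, ": ",
                 paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", ")))
  }
  bad <- sum(vapply(seqs, function(s) {
    sum(!strsplit(s, "")[[1]] %in% c("A", "C", "G", "T", "N"))
  }, integer(1)))
  if (bad > 0L) {
    seqs <- vapply(seqs, function(s) {
      gsub("[^ACGTN]", "N", s)
    }, character(1))
    message(bad, " ambiguity code(s) other than N mapped to N in ", label)
  }
  new_assembly(seqs, label)
}

#' Construct an assembly from in-memory sequences
#'
#' @param seq named character vector of contig sequences (uppercase
#'   `A`,`C`,`G`,`T`,`N`).
#' @param label assembly label.
#' @return an `ssr_assembly` object.
#' @export
new_assembly <- function(seq, label) {
  stopifnot(is.character(seq), length(seq) >= 1L, !is.null(names(seq)),
            all(nchar(seq) > 0L), !anyDuplicated(names(seq)))
  structure(list(label = label, seq = seq), class = "ssr_assembly")
}

#' @export
print.ssr_assembly <- function(x, ...) {
  cat("<ssr_assembly> ", x$label, ": ", length(x$seq), " contig(s), ",
      format(sum(nchar(x$seq)), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

#' Contig lengths of an assembly
#'
#' @param assembly an `ssr_assembly`.
#' @return tibble with columns `contig` and `length`.
#' @export
contig_lengths <- function(assembly) {
  tibble(contig = names(assembly$seq),
         length = unname(nchar(assembly$seq)))
}

#' Write an assembly to FASTA
#'
#' @param assembly an `ssr_assembly`.
#' @param path output path; `.gz` suffix triggers compression.
#' @return `path`, invisibly.
#' @export
write_assembly <- function(assembly, path) {
  dss <- Biostrings::DNAStringSet(assembly$seq)
  Biostrings::writeXStringSet(dss, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

# Extract [start, end] (1-based inclusive) from one contig.
extract_seq <- function(assembly, contig, start, end) {
  s <- assembly$seq[[contig]]
  stopifnot(start >= 1L, end <= nchar(s), start <= end)
  substr(s, start, end)
}

# Coerce a mixed list of paths / ssr_assembly objects into assemblies.
as_assembly_list <- function(assemblies, labels = NULL) {
  out <- vector("list", length(assemblies))
  for (i in seq_along(assemblies)) {
    a <- assemblies[[i]]
    if (inherits(a, "ssr_assembly")) {
      out[[i]] <- a
    } else if (is.character(a) && length(a) == 1L) {
      out[[i]] <- read_assembly(a, label = if (!is.null(labels)) labels[i] else NULL)
    } else {
      abort("assemblies must be file paths or ssr_assembly objects")
    }
  }
  labs <- vapply(out, `[[`, character(1), "label")
  if (anyDuplicated(labs)) abort("assembly labels must be unique")
  out
}
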