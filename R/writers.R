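#' Coordinate layout of an assembly
#'
#' Expands a `hic_assembly` into one row per placed component: which output
#' object it lands in, at which (0-based, half-open) coordinates, and in
#' which orientation, assuming `gap_n` Ns between consecutive components.
#' All writers derive from this table, which guarantees that FASTA, chain
#' and AGP output describe the same embedding.
#'
#' @param assembly a `hic_assembly`.
#' @param lengths named numeric vector of input scaffold lengths (bp).
#' @param gap_n gap size between consecutive components.
#' @return data.frame with columns `object`, `object_length`, `component`,
#'   `comp_length`, `strand`, `obj_start`, `obj_end`, `part`.
#' @export
assembly_layout <- function(assembly, lengths, gap_n = 2000) {
  records <- c(assembly$chains,
               stats::setNames(assembly$unplaced_chains,
                               if (length(assembly$unplaced_chains))
                                 sprintf("unplaced_hic_scaffold_%d",
                                         seq_along(assembly$unplaced_chains))
                               else character()),
               stats::setNames(
                 lapply(assembly$unplaced_originals, function(s)
                   data.frame(scaffold_id = s, orientation = "+",
                              stringsAsFactors = FALSE)),
                 assembly$unplaced_originals))
  out <- lapply(names(records), function(nm) {
    ch <- records[[nm]]
    ll <- lengths[ch$scaffold_id]
    if (anyNA(ll)) stop("missing length for scaffold: ",
                        paste(ch$scaffold_id[is.na(ll)], collapse = ", "))
    starts <- cumsum(c(0, head(ll, -1) + gap_n))
    data.frame(object = nm,
               object_length = sum(ll) + gap_n * (nrow(ch) - 1),
               component = ch$scaffold_id, comp_length = as.numeric(ll),
               strand = ch$orientation,
               obj_start = starts, obj_end = starts + ll,
               part = seq_len(nrow(ch)), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write the assembly as FASTA
#'
#' One record per Hi-C scaffold; the header is the record id followed by a
#' comma-separated description of the component scaffolds and their
#' orientations (e.g. `>hic_scaffold_1 A:+,B:-`). Reverse-oriented
#' components are reverse-complemented and consecutive components are
#' separated by exactly `gap_n` `N` characters. Unplaced originals are
#' emitted unchanged under their own ids.
#'
#' @param assembly a `hic_assembly`.
#' @param sequences named character vector or [Biostrings::DNAStringSet] of
#'   input scaffold sequences.
#' @param path output file.
#' @param gap_n number of Ns between joined scaffolds.
#' @param width FASTA line width.
#' @return `path`, invisibly.
#' @export
write_assembly_fasta <- function(assembly, sequences, path, gap_n = 2000,
                                 width = 80) {
  if (!inherits(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(unlist(as.list(sequences)))
  lengths <- stats::setNames(Biostrings::width(sequences), names(sequences))
  lay <- assembly_layout(assembly, lengths, gap_n)
  missing <- setdiff(lay$component, names(sequences))
  if (length(missing)) stop("missing sequence for scaffold: ",
                            paste(missing, collapse = ", "))
  recs <- vapply(split(lay, lay$object), function(sub) {
    sub <- sub[order(sub$part), ]
    pieces <- vapply(seq_len(nrow(sub)), function(k) {
      s <- sequences[[sub$component[k]]]
      if (sub$strand[k] == "-") s <- Biostrings::reverseComplement(s)
      as.character(s)
    }, character(1))
    paste(pieces, collapse = strrep("N", gap_n))
  }, character(1))
  objs <- unique(lay$object)
  descr <- vapply(objs, function(o) {
    sub <- lay[lay$object == o, ]
    paste0(sub$component[order(sub$part)], ":",
           sub$strand[order(sub$part)], collapse = ",")
  }, character(1))
  out <- Biostrings::DNAStringSet(recs[objs])
  names(out) <- paste(objs, descr)
  Biostrings::writeXStringSet(out, path, width = width)
  invisible(path)
}

#' Write a UCSC liftover chain file
#'
#' One chain per placed component, mapping original scaffold coordinates
#' (target) to assembly coordinates (query). Reverse-oriented components
#' get query strand `-` with coordinates in reverse-complement space, per
#' the chain specification, so lifting any original interval through the
#' chain and back is the identity.
#'
#' @param assembly a `hic_assembly`.
#' @param lengths named numeric vector of input scaffold lengths.
#' @param path output file.
#' @param gap_n gap size used when laying out the assembly.
#' @return `path`, invisibly.
#' @export
write_chain_file <- function(assembly, lengths, path, gap_n = 2000) {
  lay <- assembly_layout(assembly, lengths, gap_n)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(lay))) {
    len <- lay$comp_length[k]
    qsize <- lay$object_length[k]
    if (lay$strand[k] == "+") {
      qs <- lay$obj_start[k]; qe <- lay$obj_end[k]
    } else {
      qs <- qsize - lay$obj_end[k]; qe <- qsize - lay$obj_start[k]
    }
    writeLines(sprintf("chain %d %s %d + 0 %d %s %d %s %d %d %d",
                       as.integer(len), lay$component[k], as.integer(len),
                       as.integer(len), lay$object[k], as.integer(qsize),
                       lay$strand[k], as.integer(qs), as.integer(qe), k),
               con)
    writeLines(sprintf("%d", as.integer(len)), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write an AGP (v2.1) placement table
#'
#' `W` rows describe component placements (1-based inclusive coordinates)
#' and `U` rows describe the 2000-bp scaffold gaps between them, with
#' proximity-ligation evidence.
#'
#' @inheritParams write_chain_file
#' @return `path`, invisibly.
#' @export
write_agp <- function(assembly, lengths, path, gap_n = 2000) {
  lay <- assembly_layout(assembly, lengths, gap_n)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  for (o in unique(lay$object)) {
    sub <- lay[lay$object == o, ]
    sub <- sub[order(sub$part), ]
    part_no <- 0L
    for (k in seq_len(nrow(sub))) {
      if (k > 1) {
        part_no <- part_no + 1L
        gap_beg <- sub$obj_end[k - 1] + 1
        writeLines(paste(o, as.integer(gap_beg),
                         as.integer(gap_beg + gap_n - 1), part_no,
                         "U", gap_n, "scaffold", "yes",
                         "proximity_ligation", sep = "\t"), con)
      }
      part_no <- part_no + 1L
      writeLines(paste(o, as.integer(sub$obj_start[k] + 1),
                       as.integer(sub$obj_end[k]), part_no,
                       "W", sub$component[k], 1L,
                       as.integer(sub$comp_length[k]), sub$strand[k],
                       sep = "\t"), con)
    }
  }
  invisible(path)
}
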