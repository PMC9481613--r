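#' Write insertion variants as a minimal VCF 4.2
#'
#' One record per insertion: `POS = breakpoint_left`, `REF` the base at the
#' breakpoint, `ALT = REF + inserted_seq`. Duplication annotations, when
#' supplied, are carried in INFO keys `DUP_TEMPLATE` (c.-X_-Y region),
#' `DUP_LEN`, `NONTEMPLATED` and `CANONICAL` (0/1).
#'
#' @param insertions data.frame with columns `breakpoint_left`,
#'   `inserted_seq`; optional columns `id`, `dup_template`, `dup_len`,
#'   `nontemplated`, `canonical`.
#' @param path output file.
#' @param ref optional [promoter_reference()] supplying REF bases (else `N`).
#' @param contig contig label for the header and CHROM column.
#' @return `path`, invisibly.
#' @export
write_insertions_vcf <- function(insertions, path, ref = NULL, contig = "chr5") {
  df <- as.data.frame(insertions)
  stopifnot(all(c("breakpoint_left", "inserted_seq") %in% names(df)))
  df <- df[order(df$breakpoint_left), , drop = FALSE]
  refbase <- vapply(df$breakpoint_left, function(p) {
    if (!is.null(ref) && p >= ref$start_genomic && p <= ref_end(ref)) {
      ref_subseq(ref, p, p)
    } else {
      "N"
    }
  }, character(1))
  info <- vapply(seq_len(nrow(df)), function(i) {
    keys <- c(
      if (!is.null(df$dup_template) && !is.na(df$dup_template[i])) {
        paste0("DUP_TEMPLATE=", df$dup_template[i])
      },
      if (!is.null(df$dup_len) && !is.na(df$dup_len[i])) {
        paste0("DUP_LEN=", df$dup_len[i])
      },
      if (!is.null(df$nontemplated) && !is.na(df$nontemplated[i])) {
        paste0("NONTEMPLATED=", df$nontemplated[i])
      },
      if (!is.null(df$canonical) && !is.na(df$canonical[i])) {
        paste0("CANONICAL=", as.integer(df$canonical[i]))
      }
    )
    if (is.null(keys)) "." else paste(keys, collapse = ";")
  }, character(1))
  ids <- if (is.null(df$id)) rep(".", nrow(df)) else df$id
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=tertdup",
    paste0("##contig=<ID=", contig, ">"),
    '##INFO=<ID=DUP_TEMPLATE,Number=1,Type=String,Description="Duplicated region, c.-X_-Y relative to the TERT ATG">',
    '##INFO=<ID=DUP_LEN,Number=1,Type=Integer,Description="Insert length in bp">',
    '##INFO=<ID=NONTEMPLATED,Number=1,Type=Integer,Description="Nontemplated junction bases">',
    '##INFO=<ID=CANONICAL,Number=1,Type=Integer,Description="1 if the record is left-aligned canonical">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- if (nrow(df)) {
    paste(
      contig, df$breakpoint_left, ids, refbase,
      paste0(refbase, df$inserted_seq), ".", ".", info,
      sep = "\t"
    )
  } else {
    character()
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read insertion variants from a VCF
#'
#' Accepts the minimal insertion records written by
#' [write_insertions_vcf()] (and any VCF whose ALT extends REF on the right).
#' Uses the vcfR parser when available, else a plain-text fallback.
#'
#' @param path VCF file.
#' @return data.frame with columns `chrom`, `breakpoint_left`,
#'   `inserted_seq`, `id`, `info`.
#' @export
read_insertions_vcf <- function(path) {
  if (!any(!startsWith(readLines(path), "#"))) {
    return(empty_vcf_df())
  }
  if (requireNamespace("vcfR", quietly = TRUE)) {
    v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
    fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE), stringsAsFactors = FALSE)
    if (nrow(fix) == 0) {
      return(empty_vcf_df())
    }
    chrom <- fix$CHROM
    pos <- as.integer(fix$POS)
    refa <- fix$REF
    alt <- fix$ALT
    id <- fix$ID
    info <- fix$INFO
  } else {
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "#")]
    if (!length(body)) {
      return(empty_vcf_df())
    }
    f <- do.call(rbind, strsplit(body, "\t"))
    chrom <- f[, 1]
    pos <- as.integer(f[, 2])
    id <- f[, 3]
    refa <- f[, 4]
    alt <- f[, 5]
    info <- f[, 8]
  }
  if (any(substr(alt, 1L, nchar(refa)) != refa)) {
    stop("VCF contains records whose ALT does not extend REF (not simple insertions)")
  }
  data.frame(
    chrom = chrom,
    breakpoint_left = pos + nchar(refa) - 1L,
    inserted_seq = substring(alt, nchar(refa) + 1L),
    id = id,
    info = info,
    stringsAsFactors = FALSE
  )
}

empty_vcf_df <- function() {
  data.frame(
    chrom = character(), breakpoint_left = integer(),
    inserted_seq = character(), id = character(), info = character(),
    stringsAsFactors = FALSE
  )
}

#' Write a TSV report
#' @param df data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a JSON summary
#' @param x list or data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_json_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
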