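#' Parse an Ensembl-style peptide FASTA into a protein catalog
#'
#' Reads a peptide FASTA whose headers carry Ensembl pep \code{key:value}
#' attributes and builds a \linkS4class{ProteinCatalog}. The first header
#' token is the protein accession; \code{gene:}, \code{transcript:} and
#' \code{transcript_biotype:} attributes are required, \code{gene_symbol:}
#' is optional. Sequence lengths are counted after stripping a single
#' terminal stop character (\code{*}); an internal \code{*} is an error
#' because lengths feed the coverage terms of the pair scores.
#'
#' No biotype filtering is applied here; see \code{\link{filterByBiotype}}.
#'
#' @param path path to a (possibly gzipped) peptide FASTA file.
#' @return A \linkS4class{ProteinCatalog} with all entries in
#'   \code{keptRecords} and an empty excluded set.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(
#'   ">P1 pep gene:G1 transcript:T1 transcript_biotype:protein_coding gene_symbol:UBE2D1",
#'   "MKV*"), fa)
#' cat <- readProteinFasta(fa)
#' keptRecords(cat)$seq_length  # 3
#' @export
readProteinFasta <- function(path) {
    if (!file.exists(path)) stop("FASTA file not found: ", path)
    aa <- Biostrings::readAAStringSet(path)
    if (length(aa) == 0L) stop("empty FASTA file: ", path)
    headers <- names(aa)
    seqs <- as.character(aa)

    recs <- lapply(seq_along(headers), function(i) {
        header <- headers[[i]]
        tokens <- strsplit(trimws(header), "\\s+")[[1L]]
        pid <- tokens[[1L]]
        attrs <- .parseHeaderAttrs(tokens[-1L])
        for (need in c("gene", "transcript", "transcript_biotype")) {
            if (is.na(attrs[[need]]))
                stop(sprintf("FASTA record '%s': missing '%s:' attribute in header: >%s",
                             pid, need, header))
        }
        s <- seqs[[i]]
        s <- sub("\\*$", "", s)
        if (grepl("\\*", s, fixed = FALSE))
            stop(sprintf("FASTA record '%s': internal stop codon '*' in sequence",
                         pid))
        if (nchar(s) < 1L)
            stop(sprintf("FASTA record '%s': empty sequence", pid))
        list(protein_id = pid, transcript_id = attrs[["transcript"]],
             gene_id = attrs[["gene"]], gene_symbol = attrs[["gene_symbol"]],
             transcript_biotype = attrs[["transcript_biotype"]],
             seq_length = nchar(s))
    })

    df <- DataFrame(
        protein_id = vapply(recs, `[[`, character(1), "protein_id"),
        transcript_id = vapply(recs, `[[`, character(1), "transcript_id"),
        gene_id = vapply(recs, `[[`, character(1), "gene_id"),
        gene_symbol = vapply(recs, `[[`, character(1), "gene_symbol"),
        transcript_biotype = vapply(recs, `[[`, character(1),
                                    "transcript_biotype"),
        seq_length = vapply(recs, `[[`, integer(1), "seq_length"))
    dup <- df$protein_id[duplicated(df$protein_id)]
    if (length(dup))
        stop("duplicate protein accession(s) in FASTA: ",
             paste(unique(dup), collapse = ", "))
    dupT <- df$transcript_id[duplicated(df$transcript_id)]
    if (length(dupT))
        stop("duplicate transcript id(s) in FASTA: ",
             paste(unique(dupT), collapse = ", "))
    ProteinCatalog(df)
}

.parseHeaderAttrs <- function(tokens) {
    out <- c(gene = NA_character_, transcript = NA_character_,
             transcript_biotype = NA_character_, gene_symbol = NA_character_)
    hit <- grepl("^[A-Za-z_]+:", tokens)
    for (tok in tokens[hit]) {
        key <- sub(":.*$", "", tok)
        if (key %in% names(out))
            out[[key]] <- sub("^[A-Za-z_]+:", "", tok)
    }
    out
}

#' Default excluded transcript biotypes
#'
#' Nonsense-mediated-decay transcripts never reach the ribosome, polymorphic
#' pseudogenes may yield non-functional proteins, and T-cell receptor /
#' immunoglobulin genes have target-specific affinities despite high mutual
#' similarity; none are grouped, but their transcripts are passed through
#' with their original expression. Entries ending in \code{*} are prefix
#' patterns.
#'
#' @return character vector of biotype patterns.
#' @export
defaultBiotypeExclusions <- function() {
    c("nonsense_mediated_decay", "polymorphic_pseudogene", "TR_*", "IG_*")
}

.canonBiotype <- function(x) gsub("[^a-z0-9*]", "", tolower(x))

.biotypeExcluded <- function(biotypes, exclusions) {
    if (!length(exclusions)) return(rep(FALSE, length(biotypes)))
    canon <- .canonBiotype(biotypes)
    exCanon <- .canonBiotype(exclusions)
    hit <- rep(FALSE, length(biotypes))
    for (ex in exCanon) {
        if (endsWith(ex, "*")) {
            hit <- hit | startsWith(canon, sub("\\*$", "", ex))
        } else {
            hit <- hit | canon == ex
        }
    }
    hit
}

#' Move excluded-biotype records out of the kept set
#'
#' Records whose transcript biotype matches an exclusion are moved to the
#' catalog's excluded set: they take no part in pairing or grouping but are
#' retained so their transcripts keep their original expression in the
#' recalculated output. Matching is case-insensitive and tolerant of
#' underscore dialect drift (\code{nonsense_mediated_decay} and
#' \code{non_sense_mediated_decay} are the same biotype).
#'
#' @param catalog a \linkS4class{ProteinCatalog}.
#' @param exclusions character vector of biotypes; entries ending in
#'   \code{*} are prefix patterns. Defaults to
#'   \code{\link{defaultBiotypeExclusions}}.
#' @return the filtered \linkS4class{ProteinCatalog}.
#' @export
filterByBiotype <- function(catalog, exclusions = defaultBiotypeExclusions()) {
    stopifnot(is(catalog, "ProteinCatalog"))
    recs <- catalog@records
    drop <- .biotypeExcluded(recs$transcript_biotype, exclusions)
    ProteinCatalog(recs[!drop, , drop = FALSE],
                   rbind(catalog@excluded, recs[drop, , drop = FALSE]))
}

#' Categorize a protein pair by the origin of its gene symbols
#'
#' Pairs are classed as \code{same_gene} (equal non-empty symbols),
#' \code{same_gene_family} (equal family stems), \code{different_gene_family}
#' or \code{undefined}. A symbol is uninformative (\code{undefined}) when
#' absent, all-digit, or a clone-style accession with a version suffix
#' (e.g. \code{AC012345.1}). The family stem upper-cases the symbol, strips
#' a trailing \code{-NNN} transcript suffix, then strips either the trailing
#' digits (UBE2D1 -> UBE2D) or one trailing letter (HIST1H1A -> HIST1H1),
#' so paralog series like HIST1H1A-E and UBE2D1-4 fall into one family
#' without an external family database.
#'
#' @param symbolA,symbolB character vectors of gene symbols (recycled;
#'   \code{NA} or \code{""} means absent).
#' @return character vector with one category per pair.
#' @examples
#' categorizePair("HIST1H1A", "HIST1H1E")  # same_gene_family
#' categorizePair("AC012345.1", "UBE2D1")  # undefined
#' @export
categorizePair <- function(symbolA, symbolB) {
    n <- max(length(symbolA), length(symbolB))
    a <- rep_len(as.character(symbolA), n)
    b <- rep_len(as.character(symbolB), n)
    aU <- toupper(a); bU <- toupper(b)
    out <- rep("different_gene_family", n)
    sameGene <- !is.na(a) & !is.na(b) & nzchar(a) & nzchar(b) & aU == bU
    undef <- .uninformativeSymbol(a) | .uninformativeSymbol(b)
    stemA <- .familyStem(aU); stemB <- .familyStem(bU)
    sameFam <- !undef & nzchar(stemA) & nzchar(stemB) & stemA == stemB
    out[sameFam] <- "same_gene_family"
    out[undef] <- "undefined"
    out[sameGene] <- "same_gene"
    out
}

.uninformativeSymbol <- function(sym) {
    is.na(sym) | !nzchar(sym) |
        grepl("^[0-9]+$", sym) |
        grepl("^[A-Za-z]+[0-9]+\\.[0-9]+$", sym)
}

.familyStem <- function(symUpper) {
    s <- sub("-[0-9]+$", "", symUpper)
    sub("([A-Z]|[0-9]+)$", "", s)
}

#' Write / read a catalog as TSV
#'
#' Serializes both partitions with a \code{status} column
#' (\code{kept}/\code{excluded}); \code{readCatalogTsv} restores the
#' catalog losslessly.
#'
#' @param catalog a \linkS4class{ProteinCatalog}.
#' @param path output (or input) TSV path.
#' @return \code{writeCatalogTsv} returns \code{path} invisibly;
#'   \code{readCatalogTsv} returns a \linkS4class{ProteinCatalog}.
#' @export
writeCatalogTsv <- function(catalog, path) {
    stopifnot(is(catalog, "ProteinCatalog"))
    k <- as.data.frame(catalog@records)
    e <- as.data.frame(catalog@excluded)
    k$status <- rep("kept", nrow(k))
    e$status <- rep("excluded", nrow(e))
    out <- rbind(k, e)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeCatalogTsv
#' @export
readCatalogTsv <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = c(seq_length = "integer"))
    df$gene_symbol <- as.character(df$gene_symbol)
    ProteinCatalog(df[df$status == "kept", .CATALOG_COLS, drop = FALSE],
                   df[df$status == "excluded", .CATALOG_COLS, drop = FALSE])
}
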