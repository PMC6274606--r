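GENE_CATEGORIES <- c("gwas", "transcriptome", "highrisk", "control")
GENE_SPECIES <- c("human", "mouse", "rat")

#' Normalize gene symbols
#'
#' Trims surrounding whitespace and upper-cases symbols. Blank entries are
#' dropped. The operation is idempotent.
#'
#' @param x character vector of raw symbols.
#' @return character vector of normalized, non-blank symbols (duplicates are
#'   kept; de-duplication is the responsibility of [gene_set()]).
#' @export
normalize_symbols <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[nzchar(x)]
}

#' Construct an evidence gene set
#'
#' A gene set is a named list of unique, normalized human-ortholog gene
#' symbols tagged with an evidence category and the species the evidence
#' came from.
#'
#' @param symbols character vector of gene symbols (normalized and
#'   de-duplicated preserving first occurrence).
#' @param set_id short label, e.g. `"GWAS_Adult"`.
#' @param category one of `"gwas"`, `"transcriptome"`, `"highrisk"`,
#'   `"control"`.
#' @param species one of `"human"`, `"mouse"`, `"rat"`.
#' @param provenance free-text source note.
#' @param source_species species the evidence originally came from
#'   (defaults to `species`); preserved by [map_orthologs()] so that
#'   evidence-class assignment can distinguish human from rodent evidence
#'   after symbols have been converted to human orthologs.
#' @return an object of class `gene_set`.
#' @export
gene_set <- function(symbols, set_id, category, species = "human",
                     provenance = "", source_species = species) {
  category <- match.arg(category, GENE_CATEGORIES)
  species <- match.arg(species, GENE_SPECIES)
  source_species <- match.arg(source_species, GENE_SPECIES)
  raw <- if (species == "human") normalize_symbols(symbols) else {
    s <- trimws(as.character(symbols))
    s[nzchar(s)]
  }
  syms <- raw[!duplicated(if (species == "human") raw else toupper(raw))]
  if (length(syms) < 1L) {
    stop("gene set '", set_id, "' is empty after normalization",
         call. = FALSE)
  }
  structure(
    list(set_id = as.character(set_id), category = category,
         species = species, source_species = source_species,
         symbols = syms, provenance = as.character(provenance),
         n_duplicates = length(raw) - length(syms)),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s [%s, %s]: %d genes\n",
              x$set_id, x$category, x$species, length(x$symbols)))
  show <- utils::head(x$symbols, 8L)
  cat("  ", paste(show, collapse = ", "),
      if (length(x$symbols) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$symbols)

#' Read a gene list from a TSV file
#'
#' Reads the first column of a tab-separated file (one symbol per row;
#' optional header and extra columns; `#` comment lines ignored) and builds
#' a [gene_set()]. Duplicate and blank rows are counted and reported via
#' `message()` and in the `n_duplicates` field.
#'
#' @param path file path.
#' @param set_id,category,species,provenance passed to [gene_set()].
#' @param header logical; does the file have a header row?
#' @return a `gene_set`.
#' @export
read_gene_list <- function(path, set_id, category, species = "human",
                           provenance = path, header = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = header, comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = "character", blank.lines.skip = FALSE)
  raw <- if (ncol(df) >= 1L) df[[1L]] else character(0)
  n_blank <- sum(!nzchar(trimws(raw)))
  kept <- trimws(raw)[nzchar(trimws(raw))]
  if (length(kept) == 0L) {
    stop("no gene symbols left after filtering blank rows in ", path,
         call. = FALSE)
  }
  gs <- gene_set(kept, set_id = set_id, category = category,
                 species = species, provenance = provenance)
  if (gs$n_duplicates > 0L || n_blank > 0L) {
    message(sprintf("read_gene_list(%s): %d duplicate, %d blank rows dropped",
                    set_id, gs$n_duplicates, n_blank))
  }
  gs
}

#' Read an ortholog mapping table
#'
#' Three tab-separated columns: `source_symbol`, `source_species`,
#' `human_symbol`. Duplicate (source, human) pairs are collapsed.
#'
#' @param path file path.
#' @return a `data.frame` with the three columns; human symbols upper-cased.
#' @export
read_ortholog_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("source_symbol", "source_species", "human_symbol")
  if (!all(need %in% names(df))) {
    stop("ortholog table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df$human_symbol <- toupper(trimws(df$human_symbol))
  df$source_symbol <- trimws(df$source_symbol)
  df[!duplicated(df[, c("source_symbol", "human_symbol")]), need]
}

#' Map a rodent gene set to human orthologs
#'
#' Every mapped source symbol contributes all of its human targets
#' (one-to-many mappings expand; many-to-one collapse after
#' de-duplication). Matching is case-insensitive on the source symbol.
#' Unmapped symbols are dropped with a reported count, not an error.
#'
#' @param gs a rodent (`mouse` or `rat`) `gene_set`.
#' @param table an ortholog table as returned by [read_ortholog_table()].
#' @return a human-species `gene_set`; the number of unmapped source
#'   symbols is attached as attribute `n_unmapped`.
#' @export
map_orthologs <- function(gs, table) {
  stopifnot(inherits(gs, "gene_set"))
  if (!gs$species %in% c("mouse", "rat")) {
    stop("map_orthologs expects a mouse or rat gene set", call. = FALSE)
  }
  tab <- table[table$source_species == gs$species, , drop = FALSE]
  key <- toupper(tab$source_symbol)
  hits <- toupper(gs$symbols) %in% key
  n_unmapped <- sum(!hits)
  targets <- tab$human_symbol[key %in% toupper(gs$symbols)]
  if (length(targets) == 0L) {
    stop("no symbols of '", gs$set_id, "' could be mapped", call. = FALSE)
  }
  if (n_unmapped > 0L) {
    message(sprintf("map_orthologs(%s): %d of %d symbols unmapped, dropped",
                    gs$set_id, n_unmapped, length(gs$symbols)))
  }
  out <- gene_set(targets, set_id = gs$set_id, category = gs$category,
                  species = "human", source_species = gs$species,
                  provenance = paste0(gs$provenance, " [orthologs from ",
                                      gs$species, "]"))
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Read a GMT pathway collection
#'
#' Standard GMT: each line is `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Member symbols are normalized and de-duplicated as in [read_gene_list()].
#'
#' @param path file path.
#' @param collection_id label for the collection (default: file basename).
#' @return an object of class `pathway_collection`: a named list of
#'   character vectors with a `collection_id` attribute.
#' @export
read_gmt <- function(path, collection_id = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  pw <- vector("list", length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop("malformed GMT line ", i, " in ", path,
           ": fewer than 3 tab-separated fields", call. = FALSE)
    }
    nm[i] <- trimws(f[1L])
    syms <- normalize_symbols(f[-(1:2)])
    pw[[i]] <- unique(syms)
    if (length(pw[[i]]) == 0L) {
      stop("empty pathway '", nm[i], "' at GMT line ", i, call. = FALSE)
    }
  }
  if (anyDuplicated(nm)) stop("duplicate pathway names in ", path,
                              call. = FALSE)
  pathway_collection(stats::setNames(pw, nm), collection_id)
}

#' Construct a pathway collection
#' @param pathways named list of character vectors (unique uppercase
#'   symbols per pathway).
#' @param collection_id label.
#' @return a `pathway_collection`.
#' @export
pathway_collection <- function(pathways, collection_id = "collection") {
  stopifnot(is.list(pathways), !is.null(names(pathways)))
  if (any(lengths(pathways) == 0L)) stop("every pathway must be non-empty",
                                         call. = FALSE)
  if (anyDuplicated(names(pathways))) stop("pathway names must be unique",
                                           call. = FALSE)
  structure(pathways, class = "pathway_collection",
            collection_id = collection_id)
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("<pathway_collection> %s: %d pathways, sizes %d-%d\n",
              attr(x, "collection_id"), length(x),
              min(lengths(x)), max(lengths(x))))
  invisible(x)
}

#' Write a pathway collection to a GMT file
#' @param pc a `pathway_collection`.
#' @param path output path.
#' @export
write_gmt <- function(pc, path) {
  lines <- vapply(names(pc), function(nm) {
    paste(c(nm, "na", pc[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an interaction network from an edge-list or SIF file
#'
#' Accepts two-column (`node_a`, `node_b`) or three-column SIF
#' (`node_a`, `relation`, `node_b`) tab- or whitespace-separated rows.
#' Produces an undirected simple graph: duplicate edges are collapsed and
#' self-loops dropped (with a message).
#'
#' @param path file path.
#' @return an [igraph::igraph] object.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    warning("empty edge list: ", path, call. = FALSE)
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  ends <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[[i]]), "[\t ]+")[[1L]]
    if (length(f) == 2L) f else if (length(f) >= 3L) f[c(1L, 3L)] else {
      stop("malformed edge row ", i, " in ", path,
           ": expected 2 (edge list) or 3 (SIF) fields", call. = FALSE)
    }
  })
  em <- do.call(rbind, ends)
  loops <- em[, 1L] == em[, 2L]
  if (any(loops)) {
    message(sprintf("read_edge_list: dropped %d self-loop(s)", sum(loops)))
    em <- em[!loops, , drop = FALSE]
  }
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a data frame as TSV with deterministic layout
#'
#' @param records a `data.frame`.
#' @param path output path.
#' @param sort_by character vector of column names to sort rows by (columns
#'   prefixed with `-` sort descending); `NULL` keeps input order.
#' @param allow_empty allow zero rows?
#' @export
write_table <- function(records, path, sort_by = NULL, allow_empty = FALSE) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L && !allow_empty) {
    stop("refusing to write empty table to ", path,
         " (set allow_empty = TRUE)", call. = FALSE)
  }
  if (!is.null(sort_by) && nrow(records) > 0L) {
    keys <- lapply(sort_by, function(k) {
      desc <- startsWith(k, "-")
      col <- records[[sub("^-", "", k)]]
      if (desc) {
        if (is.numeric(col)) -col else -xtfrm(col)
      } else xtfrm(col)
    })
    records <- records[do.call(order, keys), , drop = FALSE]
  }
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a gene set as a one-column TSV
#' @param gs a `gene_set`.
#' @param path output path.
#' @export
write_gene_list <- function(gs, path) {
  write_table(data.frame(symbol = gs$symbols), path)
}
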