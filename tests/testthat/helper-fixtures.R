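# Small in-code fixtures shared across test files.

make_set <- function(symbols, id = "S", category = "gwas",
                     species = "human", ...) {
  gene_set(symbols, set_id = id, category = category, species = species,
           ...)
}

# Exhaustive-enumeration oracle for the hypergeometric upper tail:
# walks every possible overlap value and sums exact pmf terms computed
# with choose(); only usable for small N.
enum_upper_tail <- function(N, K, n, k) {
  kmax <- min(K, n)
  if (k <= max(0, K + n - N)) return(1)
  i <- seq.int(k, kmax)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Hand implementation of the Benjamini-Hochberg step-up rule.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Writes a character vector as a temp file and returns the path.
tmp_lines <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# A tiny ortholog table covering mouse and rat test symbols.
toy_ortholog_table <- function() {
  data.frame(
    source_symbol = c("Mecp2", "Maoa", "GeneA", "GeneA", "GeneB", "Avpr1a"),
    source_species = c("mouse", "mouse", "mouse", "mouse", "mouse", "rat"),
    human_symbol = c("MECP2", "MAOA", "H1", "H2", "H1", "AVPR1A"),
    stringsAsFactors = FALSE)
}

# Table-1 style printed pairs: sizes, overlap, published p (bound).
published_overlaps <- function() {
  data.frame(
    n_a = c(175, 281, 89, 381, 89, 271, 271, 397, 211),
    n_b = c(281, 89, 85, 89, 211, 397, 381, 281, 397),
    k = c(6, 4, 4, 6, 6, 12, 13, 11, 10),
    p_published = c(0.038, 0.037, 0.001, 0.007, 0.0001, 0.013, 0.002,
                    0.029, 0.010))
}
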