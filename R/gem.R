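#' Construct a canonical molecule table
#'
#' A molecule table is the long-form ("GEM") representation of spatial
#' gene expression: one record per (gene, spot) with a positive molecule
#' count.  Canonicalisation aggregates duplicate `(gene, x, y)` records
#' by summing counts; the total molecule count is preserved.
#'
#' @param gene Character vector of gene identifiers.
#' @param x,y Integer 0-based spot coordinates (column / row).
#' @param count Positive integer molecule counts.
#' @return A `data.table` of class `molecule_table` with columns
#'   `gene`, `x`, `y`, `count`, sorted by gene then y then x.
#' @export
molecule_table <- function(gene = character(), x = integer(),
                           y = integer(), count = integer()) {
  dt <- data.table::data.table(gene = as.character(gene),
                               x = as.integer(x), y = as.integer(y),
                               count = as.integer(count))
  if (nrow(dt)) {
    if (any(dt$x < 0) || any(dt$y < 0)) stop("spot coordinates must be nonnegative")
    if (any(dt$count < 1)) stop("counts must be >= 1")
    dt <- dt[, list(count = sum(count)), by = c("gene", "y", "x")]
    data.table::setcolorder(dt, c("gene", "x", "y", "count"))
    data.table::setorder(dt, gene, y, x)
  }
  data.table::setattr(dt, "class", c("molecule_table", class(dt)))
  dt[]
}

#' Total molecule count of a molecule table
#' @param molecules A [molecule_table()].
#' @return Integer total of the `count` column.
#' @export
total_count <- function(molecules) {
  if (nrow(molecules) == 0L) return(0L)
  sum(molecules$count)
}

.gem_gene_names  <- c("geneid", "gene", "gene_id", "genename")
.gem_count_names <- c("midcount", "midcounts", "umicount", "umicounts", "count", "counts")

#' Read a GEM TSV file into a molecule table
#'
#' GEM files are tab-separated with a header row; lines starting with
#' `#` are metadata and skipped.  Accepted column spellings:
#' gene = `geneID`/`gene`/`gene_id`, count =
#' `MIDCount`/`MIDCounts`/`UMICount`/`count` (case-insensitive), plus
#' literal `x` and `y`.  Extra columns are ignored on read.  Duplicate
#' `(gene, x, y)` records are summed.
#'
#' @param path Path to the GEM TSV.
#' @return A [molecule_table()].
#' @export
read_gem <- function(path) {
  if (!file.exists(path)) stop("GEM file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta <- startsWith(lines, "#")
  body <- lines[!meta]
  if (length(body) == 0L) stop("GEM file has no header row: ", path)
  dt <- data.table::fread(text = body, sep = "\t", header = TRUE,
                          colClasses = list(character = 1L), showProgress = FALSE)
  nm <- tolower(names(dt))
  pick <- function(cands, what) {
    i <- which(nm %in% cands)
    if (length(i) == 0L) stop("missing column ", what)
    i[1]
  }
  gi <- pick(.gem_gene_names, "gene")
  xi <- pick("x", "x"); yi <- pick("y", "y")
  ci <- pick(.gem_count_names, "count")
  if (nrow(dt) == 0L) return(molecule_table())
  for (col in c(xi, yi, ci)) {
    v <- dt[[col]]
    if (!is.numeric(v) || any(v != round(v))) {
      bad <- if (is.numeric(v)) which(v != round(v))[1] else 1L
      # line number in the original file: header + metadata lines before it
      stop(sprintf("non-integer value in column '%s' at data line %d",
                   names(dt)[col], bad))
    }
  }
  molecule_table(gene = dt[[gi]], x = dt[[xi]], y = dt[[yi]], count = dt[[ci]])
}

#' Write a molecule table as a GEM TSV
#'
#' @param molecules A [molecule_table()].
#' @param path Output path.
#' @param labels Optional integer vector (one per record) appended as a
#'   `label` column (0 = unassigned), producing a labelled GEM.
#' @return Invisibly, `path`.
#' @export
write_gem <- function(molecules, path, labels = NULL) {
  out <- data.table::data.table(geneID = molecules$gene, x = molecules$x,
                                y = molecules$y, MIDCount = molecules$count)
  if (!is.null(labels)) {
    if (length(labels) != nrow(molecules)) stop("labels length must match record count")
    out$label <- as.integer(labels)
  }
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Rasterise a molecule table into an expression map
#'
#' Produces the spatial expression "map": a raster of shape
#' `(max_y + 1, max_x + 1)` whose pixel `(y, x)` holds the total
#' molecule count at that spot, summed over genes.  The pixel sum equals
#' the table's total count.
#'
#' @param molecules A canonical [molecule_table()].
#' @param shape Optional `(h, w)` to force the output extent (must cover
#'   all spots).
#' @return Numeric matrix.
#' @export
gem_to_map <- function(molecules, shape = NULL) {
  if (nrow(molecules) == 0L) stop("cannot infer map extent from an empty molecule table")
  if (is.null(shape)) shape <- c(max(molecules$y) + 1L, max(molecules$x) + 1L)
  if (max(molecules$y) >= shape[1] || max(molecules$x) >= shape[2])
    stop("shape does not cover all spots")
  m <- matrix(0, shape[1], shape[2])
  idx <- molecules$y + 1L + as.numeric(molecules$x) * shape[1]
  agg <- rowsum(as.numeric(molecules$count), idx)
  m[as.numeric(rownames(agg))] <- agg[, 1]
  m
}
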