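#' Gene sets
#'
#' An unsigned gene set is a named list of gene identifiers and is scored by
#' [mean_signature_score()]; a signed gene set pairs an up-regulated with a
#' down-regulated list and is scored by the within-sample [contrast_t_score()].
#'
#' @param name Set name.
#' @param genes,up_genes,down_genes Character vectors of gene identifiers,
#'   matched case-sensitively against expression matrix rownames.
#' @return A `gene_set` or `signed_gene_set` object.
#' @examples
#' gene_set("DUX4_targets", c("ZSCAN4", "TRIM43", "MBD3L2"))
#' @export
gene_set <- function(name, genes) {
  genes <- as.character(genes)
  if (length(genes) == 0) abort(paste0("Gene set '", name, "' is empty."))
  if (anyDuplicated(genes)) {
    abort(paste0("Gene set '", name, "' contains duplicate genes."))
  }
  structure(list(name = name, genes = genes), class = "gene_set")
}

#' @rdname gene_set
#' @export
signed_gene_set <- function(name, up_genes, down_genes) {
  up_genes <- as.character(up_genes)
  down_genes <- as.character(down_genes)
  if (length(up_genes) == 0 || length(down_genes) == 0) {
    abort(paste0("Signed gene set '", name, "' needs non-empty up and down lists."))
  }
  if (anyDuplicated(up_genes) || anyDuplicated(down_genes)) {
    abort(paste0("Signed gene set '", name, "' contains duplicate genes."))
  }
  both <- intersect(up_genes, down_genes)
  if (length(both) > 0) {
    abort(paste0(
      "Signed gene set '", name, "': genes in both up and down lists: ",
      toString(head(both, 5))
    ))
  }
  structure(list(name = name, up_genes = up_genes, down_genes = down_genes),
    class = "signed_gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' @export
print.signed_gene_set <- function(x, ...) {
  cat(sprintf(
    "<signed_gene_set> %s: %d up / %d down genes\n",
    x$name, length(x$up_genes), length(x$down_genes)
  ))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name TAB description TAB gene TAB gene ...`.
#' The description field is discarded. Duplicate genes within a line are
#' collapsed with a warning; duplicate set names are an error.
#'
#' @param path File path.
#' @return Named list of [gene_set] objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- vector("list", length(fields))
  names_seen <- character(0)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3) {
      abort(sprintf("GMT line %d has %d field(s); need name, description, >=1 gene", i, length(f)))
    }
    nm <- f[1]
    if (nm %in% names_seen) {
      abort(paste0("Duplicate gene set name in ", path, ": '", nm, "'"))
    }
    names_seen <- c(names_seen, nm)
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warn(paste0("Gene set '", nm, "': duplicate genes collapsed."))
      genes <- unique(genes)
    }
    sets[[i]] <- gene_set(nm, genes)
  }
  names(sets) <- names_seen
  sets
}

#' Write gene sets to a GMT file
#'
#' A [signed_gene_set] is written as two lines, `<name>_UP` and `<name>_DOWN`.
#'
#' @param sets A [gene_set], [signed_gene_set], or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, c("gene_set", "signed_gene_set"))) sets <- list(sets)
  lines <- unlist(lapply(sets, function(s) {
    if (inherits(s, "signed_gene_set")) {
      c(
        paste(c(paste0(s$name, "_UP"), "na", s$up_genes), collapse = "\t"),
        paste(c(paste0(s$name, "_DOWN"), "na", s$down_genes), collapse = "\t")
      )
    } else {
      paste(c(s$name, "na", s$genes), collapse = "\t")
    }
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Pair `_UP`/`_DOWN` gene sets into signed sets
#'
#' Scans a list of [gene_set] objects (as returned by [read_gmt()]) for
#' matching `<name>_UP` / `<name>_DOWN` pairs and combines each pair into a
#' [signed_gene_set]; unpaired sets pass through unchanged.
#'
#' @param sets Named list of [gene_set] objects.
#' @return Named list of [gene_set] and [signed_gene_set] objects.
#' @export
pair_signed_sets <- function(sets) {
  nms <- names(sets)
  ups <- nms[grepl("_UP$", nms)]
  out <- list()
  used <- character(0)
  for (u in ups) {
    base <- sub("_UP$", "", u)
    d <- paste0(base, "_DOWN")
    if (d %in% nms) {
      out[[base]] <- signed_gene_set(base, sets[[u]]$genes, sets[[d]]$genes)
      used <- c(used, u, d)
    }
  }
  for (nm in setdiff(nms, used)) out[[nm]] <- sets[[nm]]
  out
}
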