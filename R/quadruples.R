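#' Enumerate complete ligand-receptor-TF-target cascades
#'
#' Every (ligand, receptor, tf, target) 4-tuple whose three consecutive
#' edges are present in the (pruned) network, in lexicographic order.
#'
#' @param net an `mlnet`.
#' @return data.frame (`ligand`, `receptor`, `tf`, `target`), one row per
#'   distinct 4-path.
#' @export
enumerate_quadruples <- function(net) {
  stopifnot(inherits(net, "mlnet"))
  e <- net$edges
  lr <- e[e$edge_type == "LR", c("src", "dst")]
  rt <- e[e$edge_type == "RTF", c("src", "dst")]
  tt <- e[e$edge_type == "TFT", c("src", "dst")]
  if (!nrow(lr) || !nrow(rt) || !nrow(tt))
    return(data.frame(ligand = character(), receptor = character(),
                      tf = character(), target = character()))
  names(lr) <- c("ligand", "receptor")
  names(rt) <- c("receptor", "tf")
  names(tt) <- c("tf", "target")
  q <- merge(merge(lr, rt, by = "receptor"), tt, by = "tf")
  q <- unique(q[, c("ligand", "receptor", "tf", "target")])
  q <- q[order(q$ligand, q$receptor, q$tf, q$target), ]
  rownames(q) <- NULL
  q
}

quad_key <- function(q) paste(q$ligand, q$receptor, q$tf, q$target, sep = "|")

#' Grade-specific and shared quadruples
#'
#' Set difference / intersection on the plain 4-tuples (any extra columns
#' are ignored in the comparison); provenance tags are set on the output.
#'
#' @param quads_a,quads_b quadruple data.frames from
#'   [enumerate_quadruples()] for the two conditions.
#' @param labels provenance labels, default `c("III_only", "IV_only",
#'   "both")`.
#' @return List `only_a`, `only_b`, `shared`, each a quadruple data.frame
#'   with a `grade_provenance` column.
#' @export
grade_specific <- function(quads_a, quads_b,
                           labels = c("III_only", "IV_only", "both")) {
  ka <- quad_key(quads_a); kb <- quad_key(quads_b)
  tag <- function(q, keep, lab) {
    out <- unique(q[keep, c("ligand", "receptor", "tf", "target"),
                    drop = FALSE])
    if (nrow(out)) out$grade_provenance <- lab
    else out$grade_provenance <- character()
    rownames(out) <- NULL
    out
  }
  list(only_a = tag(quads_a, !(ka %in% kb), labels[1]),
       only_b = tag(quads_b, !(kb %in% ka), labels[2]),
       shared = tag(quads_a, ka %in% kb, labels[3]))
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (set name, description, member genes per line).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) fgsea::gmtPathways(path)

#' Hypergeometric gene-set enrichment of cascade genes
#'
#' The query is the union of all genes appearing in the quadruples; each
#' gene set is tested for overlap enrichment with a one-sided
#' hypergeometric test over the background, with Benjamini-Hochberg
#' adjustment across sets.
#'
#' @param quads quadruple data.frame.
#' @param gene_sets named list of gene sets (e.g. from [read_gmt()]).
#' @param background background gene universe.
#' @param fdr_cut FDR flag threshold (default 0.05).
#' @return data.frame (`gene_set`, `overlap`, `set_size`,
#'   `background_size`, `p`, `fdr`, `significant`), ordered by FDR.
#' @export
enrich_genesets <- function(quads, gene_sets, background, fdr_cut = 0.05) {
  if (!length(gene_sets)) stopf("empty gene-set collection")
  query <- unique(c(quads$ligand, quads$receptor, quads$tf, quads$target))
  query <- intersect(query, background)
  N <- length(background); n_q <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), background)
    K <- length(set); ov <- length(intersect(set, query))
    p <- if (K == 0) 1 else phyper(ov - 1, K, N - K, n_q, lower.tail = FALSE)
    data.frame(gene_set = nm, overlap = ov, set_size = K,
               background_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, "BH")
  out$significant <- out$fdr < fdr_cut
  out <- out[order(out$fdr, out$p), ]
  rownames(out) <- NULL
  out
}

#' Write a quadruple table as a 5-column TSV
#'
#' @param quads quadruple data.frame (with or without provenance).
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_quadruples_tsv <- function(quads, path) {
  if (is.null(quads$grade_provenance)) quads$grade_provenance <- "NA"
  write.table(quads[, c("ligand", "receptor", "tf", "target",
                        "grade_provenance")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
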