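# PED-style pedigree input and affected-only meiosis counting.

#' Read a PED-style pedigree file with carrier status
#'
#' Tab-delimited, no header, seven columns: family, individual, father,
#' mother, sex, affection (1 = unaffected, 2 = affected, 0 = unknown), and
#' carrier status (0 = unknown, 1 = noncarrier, 2 = carrier). `0` denotes a
#' missing parent.
#'
#' @param path Path to the PED file.
#' @return Named list of per-family data frames with columns `id`, `father`,
#'   `mother`, `sex`, `affected`, `carrier`.
#' @export
read_ped <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character",
                           col.names = c("family", "id", "father", "mother",
                                         "sex", "affected", "carrier"))
  raw$sex <- as.integer(raw$sex)
  raw$affected <- as.integer(raw$affected)
  raw$carrier <- as.integer(raw$carrier)
  split(raw[, c("id", "father", "mother", "sex", "affected", "carrier")],
        raw$family)
}

#' Count informative meioses within one pedigree
#'
#' Affected-only counting: the pedigree is viewed as a graph of parent-child
#' transmission edges; each connected component containing k affected
#' genotyped carriers contributes k - 1 informative meioses. Unaffected or
#' ungenotyped individuals connect carriers but earn no credit. An affected
#' noncarrier anywhere in the pedigree indicates nonsegregation.
#'
#' @param ped One family's data frame as produced by [read_ped()].
#' @return List with `n` (informative meioses), `nonsegregation`, and
#'   `affected_carriers` (their identifiers).
#' @export
pedigree_meioses <- function(ped) {
  req <- c("id", "father", "mother", "affected", "carrier")
  if (!all(req %in% names(ped))) {
    stop("pedigree must have columns id, father, mother, affected, carrier")
  }
  ids <- as.character(ped$id)
  if (anyDuplicated(ids)) stop("duplicate individual identifiers in pedigree")
  parents <- c(as.character(ped$father), as.character(ped$mother))
  unknown <- setdiff(setdiff(parents, "0"), ids)
  if (length(unknown)) {
    stop(sprintf("unknown parent reference(s): %s",
                 paste(unknown, collapse = ", ")))
  }

  edges <- character(0)
  for (col in c("father", "mother")) {
    p <- as.character(ped[[col]])
    keep <- p != "0"
    edges <- c(edges, rbind(p[keep], ids[keep]))
  }
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(ids)
  if (length(edges)) g <- g + igraph::edges(edges)
  if (!igraph::is_dag(g)) stop("pedigree contains a cycle")

  affected <- ped$affected == 2
  carrier <- ped$carrier == 2
  noncarrier <- ped$carrier == 1
  nonseg <- any(affected & noncarrier)

  ac <- ids[affected & carrier]
  n <- 0L
  if (length(ac) >= 2) {
    comp <- igraph::components(igraph::as_undirected(g))$membership
    per_comp <- table(comp[ac])
    n <- sum(pmax(0L, as.integer(per_comp) - 1L))
  }
  list(n = as.integer(n), nonsegregation = nonseg, affected_carriers = ac)
}
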