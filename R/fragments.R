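# Registry of peptide deletion constructs with pull-down outcomes:
# the QQS truncation series against NF-YC partners, shipped as an
# editable TSV pair (fragments + parent lengths).

#' Read a fragment registry from TSV files
#'
#' @param fragmentFile TSV with header
#'   `id, parent, start, end, partner, outcome, note`
#' @param parentFile TSV with header `id, length` (length may be NA)
#' @return a [FragmentRegistry]
#' @export
readFragmentRegistry <- function(fragmentFile, parentFile) {
  fr <- utils::read.delim(fragmentFile, stringsAsFactors = FALSE,
                          na.strings = "NA")
  fr$note[is.na(fr$note)] <- ""
  pa <- utils::read.delim(parentFile, stringsAsFactors = FALSE,
                          na.strings = "NA")
  new("FragmentRegistry", parents = pa, fragments = fr)
}

#' The packaged QQS / NF-YC construct registry
#'
#' The QQS truncation series (QQS-1-12, QQS-13-47, QQS-11-59,
#' QQS-41-59, QQS-48-59 on the 59-residue parent) and the HsNF-YC
#' N-terminal construct, with their pull-down outcomes against
#' AtNF-YC4 and HsNF-YC partners.
#'
#' @return a [FragmentRegistry]
#' @examples
#' reg <- defaultFragmentRegistry()
#' fragmentLength(reg, "QQS-1-12")
#' @export
defaultFragmentRegistry <- function() {
  readFragmentRegistry(
    system.file("extdata", "qqs_fragments.tsv",
                package = "InterfaceContacts", mustWork = TRUE),
    system.file("extdata", "qqs_parents.tsv",
                package = "InterfaceContacts", mustWork = TRUE))
}

.fragmentSpans <- function(registry) {
  fr <- registry@fragments
  unique(fr[, c("id", "parent", "start", "end")])
}

#' Length of a registered fragment
#'
#' @param registry a [FragmentRegistry]
#' @param id fragment id
#' @return `end - start + 1`
#' @export
fragmentLength <- function(registry, id) {
  stopifnot(is(registry, "FragmentRegistry"))
  sp <- .fragmentSpans(registry)
  i <- match(id, sp$id)
  if (is.na(i)) stop("unknown fragment id: ", id)
  sp$end[i] - sp$start[i] + 1L
}

#' Total length of a contiguous fragment partition
#'
#' The listed fragments must tile part of one parent without overlap
#' or gap; returns the summed length (equal to the parent length when
#' the ids tile the whole parent).
#'
#' @param registry a [FragmentRegistry]
#' @param ids fragment ids
#' @return integer total
#' @export
partitionTotal <- function(registry, ids) {
  stopifnot(is(registry, "FragmentRegistry"), length(ids) >= 1)
  sp <- .fragmentSpans(registry)
  i <- match(ids, sp$id)
  if (anyNA(i))
    stop("unknown fragment id: ", paste(ids[is.na(i)], collapse = ", "))
  sp <- sp[i, , drop = FALSE]
  if (length(unique(sp$parent)) != 1)
    stop("fragments span multiple parents: ",
         paste(unique(sp$parent), collapse = ", "))
  sp <- sp[order(sp$start), , drop = FALSE]
  if (nrow(sp) > 1) {
    for (k in 2:nrow(sp)) {
      if (sp$start[k] <= sp$end[k - 1])
        stop("fragments overlap at ", sp$start[k], "-", sp$end[k - 1],
             " (", sp$id[k - 1], " vs ", sp$id[k], ")")
      if (sp$start[k] != sp$end[k - 1] + 1)
        stop("gap between positions ", sp$end[k - 1] + 1, " and ",
             sp$start[k] - 1, " (", sp$id[k - 1], " vs ", sp$id[k], ")")
    }
  }
  sum(sp$end - sp$start + 1L)
}

#' Binding outcomes and minimal binding regions for one partner
#'
#' Tabulates the outcome of every fragment tested against `partner`
#' and derives minimal binding regions: spans of binding fragments,
#' after discarding binding spans wholly contained in a non-binding
#' span and redundant binding spans that strictly contain another
#' retained binding span, merged into maximal runs.
#'
#' @param registry a [FragmentRegistry]
#' @param partner partner id (e.g. `"AtNF-YC4"`)
#' @return list: `outcomes` (data.frame id/start/end/outcome/note),
#'   `bindingFragments` (ids), `minimalRegions` (data.frame start/end)
#' @examples
#' s <- bindingSummary(defaultFragmentRegistry(), "AtNF-YC4")
#' s$minimalRegions
#' @export
bindingSummary <- function(registry, partner) {
  stopifnot(is(registry, "FragmentRegistry"))
  fr <- registry@fragments
  if (!partner %in% fr$partner)
    stop("unknown partner: ", partner)
  fr <- fr[fr$partner == partner, , drop = FALSE]
  outcomes <- fr[, c("id", "parent", "start", "end", "outcome", "note")]
  rownames(outcomes) <- NULL
  tested <- outcomes[outcomes$outcome != "not_tested", , drop = FALSE]
  binding <- tested[tested$outcome == "binds", , drop = FALSE]
  nonbinding <- tested[tested$outcome == "no_binding", , drop = FALSE]

  keep <- rep(TRUE, nrow(binding))
  for (i in seq_len(nrow(binding))) {
    inside <- nonbinding$start <= binding$start[i] &
      binding$end[i] <= nonbinding$end
    if (any(inside)) keep[i] <- FALSE
  }
  binding2 <- binding[keep, , drop = FALSE]
  # drop coarse spans strictly containing another retained binding span
  keep2 <- rep(TRUE, nrow(binding2))
  for (i in seq_len(nrow(binding2))) {
    contains <- binding2$start[i] <= binding2$start &
      binding2$end[i] >= binding2$end &
      !(binding2$start[i] == binding2$start &
        binding2$end[i] == binding2$end)
    if (any(contains)) keep2[i] <- FALSE
  }
  binding2 <- binding2[keep2, , drop = FALSE]

  regions <- data.frame(start = integer(0), end = integer(0))
  if (nrow(binding2)) {
    pos <- sort(unique(unlist(lapply(seq_len(nrow(binding2)), function(i)
      binding2$start[i]:binding2$end[i]))))
    breaks <- c(0, which(diff(pos) > 1), length(pos))
    regions <- do.call(rbind, lapply(seq_len(length(breaks) - 1), function(k)
      data.frame(start = pos[breaks[k] + 1], end = pos[breaks[k + 1]])))
  }
  list(outcomes = outcomes, bindingFragments = binding$id,
       minimalRegions = regions)
}

setMethod("show", "FragmentRegistry", function(object) {
  sp <- .fragmentSpans(object)
  cat("FragmentRegistry: ", nrow(sp), " fragment(s) of ",
      nrow(object@parents), " parent(s); partners: ",
      paste(unique(object@fragments$partner), collapse = ", "), "\n",
      sep = "")
})

#' @rdname FragmentRegistry-class
#' @param x a FragmentRegistry
#' @export
fragmentTable <- function(x) {
  stopifnot(is(x, "FragmentRegistry"))
  x@fragments
}

#' @rdname FragmentRegistry-class
#' @export
parentTable <- function(x) {
  stopifnot(is(x, "FragmentRegistry"))
  x@parents
}
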