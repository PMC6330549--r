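# End-to-end driver: chain-role configuration, per-structure contact
# maps, cross-structure comparison, peptide-to-segment alignment,
# binding-site transfer, linker report and interface character, with
# every intermediate written as TSV plus a reproducible run log.

.CHAIN_ROLES <- c("NF-YA", "NF-YB", "NF-YC", "DNA")

#' Read a pipeline run configuration
#'
#' The configuration is a YAML file with fields: `structures` (list of
#' `id`, `path`, `roles` — a chain-to-role map using roles NF-YA,
#' NF-YB, NF-YC, DNA), `segments` (list of `start`/`end` spans on the
#' NF-YB chain), `peptides` (list of `id`, `seq`, `parent_start`;
#' paired with `segments` by position), `peptide_length`,
#' `partner_roles` (default `NF-YC`), optional `mapping` (TSV path for
#' two-structure comparison), optional `cutoffs` overrides, `output`
#' directory and `seed`.
#'
#' @param path YAML file path
#' @return validated config (list)
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  validateRunConfig(yaml::read_yaml(path), dir = dirname(path))
}

#' @rdname readRunConfig
#' @param config a config list (as from the YAML)
#' @param dir base directory for relative paths
#' @export
validateRunConfig <- function(config, dir = ".") {
  if (is.null(config$structures) || !length(config$structures))
    stop("config error: no structures given")
  for (i in seq_along(config$structures)) {
    st <- config$structures[[i]]
    if (is.null(st$path)) stop("config error: structure ", i, " has no path")
    if (!file.exists(st$path)) {
      alt <- file.path(dir, st$path)
      if (file.exists(alt)) config$structures[[i]]$path <- alt
      else stop("config error: structure file not found: ", st$path)
    }
    if (is.null(st$roles) || !length(st$roles))
      stop("config error: structure ", i, " has no chain roles")
    bad <- setdiff(unlist(st$roles), .CHAIN_ROLES)
    if (length(bad))
      stop("config error: unknown chain role ", paste(bad, collapse = ", "),
           " (expected ", paste(.CHAIN_ROLES, collapse = "/"), ")")
    if (is.null(st$id)) config$structures[[i]]$id <- paste0("S", i)
  }
  if (length(config$structures) > 2)
    stop("config error: at most two structures are compared")
  for (sg in config$segments) {
    if (is.null(sg$start) || is.null(sg$end) || sg$start > sg$end)
      stop("config error: malformed segment span")
  }
  if (!is.null(config$segments) && length(config$segments) &&
      (is.null(config$peptides) ||
       length(config$peptides) != length(config$segments)))
    stop("config error: peptides must pair with segments by position")
  if (is.null(config$partner_roles)) config$partner_roles <- "NF-YC"
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$output)) config$output <- "run_output"
  if (!is.null(config$mapping) && !file.exists(config$mapping)) {
    alt <- file.path(dir, config$mapping)
    if (file.exists(alt)) config$mapping <- alt
    else stop("config error: mapping file not found: ", config$mapping)
  }
  config
}

.configCutoffs <- function(config) {
  co <- interactionCutoffs()
  ov <- config$cutoffs
  if (!is.null(ov)) {
    if (!is.null(ov$hydrophobic)) co@hydrophobic <- ov$hydrophobic
    if (!is.null(ov$ionic)) co@ionic <- ov$ionic
    if (!is.null(ov$cation_pi)) co@cationPi <- ov$cation_pi
    if (!is.null(ov$hbond_no)) co@hbondNO <- ov$hbond_no
    if (!is.null(ov$hbond_s)) co@hbondS <- ov$hbond_s
    if (!is.null(ov$dna_contact)) co@dnaContact <- ov$dna_contact
  }
  validObject(co)
  co
}

.writeTsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.3f", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the whole interface-analysis pipeline
#'
#' Executes, per configured structure: residue selection and typed
#' contact-map construction for each NF-YB segment (with DNA flags
#' when a DNA role is assigned); with two structures, the comparative
#' map through the residue mapping; then peptide-to-segment alignment,
#' binding-site transfer restricted to the partner role's chains, the
#' two-site linker report, and the interface-character summary.  Every
#' intermediate is written as TSV (numbers to 3 decimals, so repeated
#' runs are byte-identical) along with a `run_log.yaml` echoing the
#' configuration.
#'
#' @param config path to a YAML config or a config list
#' @param outDir optional output-directory override
#' @return (invisibly) list with the run directory and the in-memory
#'   results: `maps`, `comparative`, `alignments`, `proposals`,
#'   `linker`, `character`
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  else config <- validateRunConfig(config)
  if (!is.null(outDir)) config$output <- outDir
  out <- config$output
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cutoffs <- .configCutoffs(config)

  structs <- .stage("read_structures", lapply(config$structures,
    function(st) readPDB(st$path, id = st$id)))
  roleChains <- lapply(config$structures, function(st) {
    roles <- unlist(st$roles)
    split(names(roles), unname(roles))
  })

  segs <- config$segments
  if (is.null(segs) || !length(segs)) {
    warning("no segments configured; writing an empty proposal")
    empty <- new("BindingSiteProposal", peptideId = "none",
                 entries = data.frame(
                   pep_pos = integer(0), pep_res = character(0),
                   src_chain = character(0), src_seq = integer(0),
                   src_res = character(0), partner_chain = character(0),
                   partner_seq = integer(0), partner_res = character(0),
                   type = character(0), membership = character(0),
                   stringsAsFactors = FALSE))
    writeProposal(empty, file.path(out, "proposal_none.tsv"))
    .writeRunLog(config, out)
    return(invisible(list(dir = out, proposals = list(empty))))
  }

  maps <- vector("list", length(structs))
  for (si in seq_along(structs)) {
    s <- structs[[si]]
    rc <- roleChains[[si]]
    if (is.null(rc[["NF-YB"]]))
      stop("pipeline stage 'contacts' failed: structure ",
           structureId(s), " assigns no NF-YB chain", call. = FALSE)
    partnerChains <- unlist(rc[config$partner_roles])
    if (is.null(partnerChains) || !length(partnerChains))
      stop("pipeline stage 'contacts' failed: no chain with partner role ",
           paste(config$partner_roles, collapse = ","), call. = FALSE)
    dnaSet <- NULL
    if (!is.null(rc[["DNA"]])) {
      dm <- do.call(rbind, lapply(rc[["DNA"]], function(ch)
        residueMembers(selectResidues(s, ch))))
      dnaSet <- new("ResidueSet", structure = s, members = dm)
    }
    maps[[si]] <- .stage("contacts", lapply(seq_along(segs), function(k) {
      side <- selectResidues(s, rc[["NF-YB"]][1],
                             c(segs[[k]]$start, segs[[k]]$end))
      partner <- do.call(rbind, lapply(partnerChains, function(ch)
        residueMembers(selectResidues(s, ch))))
      m <- buildContactMap(side,
                           new("ResidueSet", structure = s,
                               members = partner),
                           cutoffs = cutoffs, dna = dnaSet)
      writeContactTable(m, file.path(out, sprintf("contacts_%s_seg%d.tsv",
                                                  structureId(s), k)))
      m
    }))
  }

  comp <- NULL
  if (length(structs) == 2) {
    mapping <- .stage("compare", {
      if (!is.null(config$mapping))
        utils::read.delim(config$mapping, stringsAsFactors = FALSE)
      else {
        rtA <- residueTable(structs[[1]])
        rtB <- residueTable(structs[[2]])
        keyA <- paste(rtA$chain, rtA$seqid, rtA$icode)
        keyB <- paste(rtB$chain, rtB$seqid, rtB$icode)
        shared <- intersect(keyA, keyB)
        iA <- match(shared, keyA)
        data.frame(chain_a = rtA$chain[iA], seq_a = rtA$seqid[iA],
                   icode_a = rtA$icode[iA], chain_b = rtA$chain[iA],
                   seq_b = rtA$seqid[iA], icode_b = rtA$icode[iA],
                   stringsAsFactors = FALSE)
      }
    })
    comp <- .stage("compare", lapply(seq_along(segs), function(k) {
      cm <- compareMaps(maps[[1]][[k]], maps[[2]][[k]], mapping)
      .writeTsv(comparativeTable(cm),
                file.path(out, sprintf("comparative_seg%d.tsv", k)))
      cm
    }))
  }

  pepList <- config$peptides
  alignments <- list(); proposals <- list()
  rc1 <- roleChains[[1]]
  partnerChains1 <- unlist(rc1[config$partner_roles])
  for (k in seq_along(segs)) {
    pep <- pepList[[k]]
    side <- selectResidues(structs[[1]], rc1[["NF-YB"]][1],
                           c(segs[[k]]$start, segs[[k]]$end))
    al <- .stage("align", alignSegment(
      pep$seq, residueSequence(side), classAware = TRUE,
      peptideId = pep$id,
      targetId = sprintf("NF-YB-%d-%d", segs[[k]]$start, segs[[k]]$end)))
    alignments[[k]] <- al
    .writeTsv(data.frame(peptide = pep$id, target = al$targetId,
                         offset = al$offset, score = al$score,
                         labels = paste(al$labels, collapse = ","),
                         stringsAsFactors = FALSE),
              file.path(out, sprintf("alignment_seg%d.tsv", k)))
    srcMap <- if (!is.null(comp)) comp[[k]] else maps[[1]][[k]]
    pr <- .stage("transfer", suppressMessages(transferSites(
      al, side, srcMap, partnerFilter = partnerChains1,
      peptideStart = if (is.null(pep$parent_start)) 1L
                     else pep$parent_start)))
    proposals[[k]] <- pr
    .writeTsv(proposalEntries(pr),
              file.path(out, sprintf("proposal_%s.tsv",
                                     gsub("[^A-Za-z0-9_-]", "_", pep$id))))
  }

  linker <- NULL
  if (length(proposals) == 2 &&
      nrow(proposalEntries(proposals[[1]])) &&
      nrow(proposalEntries(proposals[[2]]))) {
    linker <- .stage("linker", linkerReport(
      proposals[[1]], proposals[[2]],
      peptideLength = if (is.null(config$peptide_length)) NA_integer_
                      else config$peptide_length))
    .writeTsv(data.frame(
      n_start = linker$nSpan[1], n_end = linker$nSpan[2],
      c_start = linker$cSpan[1], c_end = linker$cSpan[2],
      linker_start = linker$linkerStart, linker_end = linker$linkerEnd,
      linker_length = linker$linkerLength,
      peptide_length = linker$peptideLength),
      file.path(out, "linker.tsv"))
  }

  charRows <- .stage("interface_character", {
    rows <- list()
    for (si in seq_along(structs)) for (k in seq_along(segs)) {
      ic <- interfaceCharacter(maps[[si]][[k]])
      for (sd in c("A", "B")) {
        cc <- ic[[sd]]$classCounts
        rows[[length(rows) + 1L]] <- data.frame(
          structure = structureId(structs[[si]]), segment = k, side = sd,
          t(as.matrix(cc)),
          hydrophobic_fraction = ic[[sd]]$hydrophobicFraction,
          label = ifelse(is.na(ic[[sd]]$label), "", ic[[sd]]$label),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  .writeTsv(charRows, file.path(out, "interface_character.tsv"))

  .writeRunLog(config, out)
  invisible(list(dir = out, maps = maps, comparative = comp,
                 alignments = alignments, proposals = proposals,
                 linker = linker, character = charRows))
}

.writeRunLog <- function(config, out) {
  log <- list(
    package = "InterfaceContacts",
    version = as.character(utils::packageVersion("InterfaceContacts")),
    seed = config$seed,
    config = config)
  yaml::write_yaml(log, file.path(out, "run_log.yaml"))
}
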