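# Hand-rolled PDB snippets and small builders used across tests.

pdb_line <- function(record = "ATOM", serial, name, resname, chain,
                     seqid, x, y, z, occ = 1, altloc = " ",
                     icode = " ", element = NULL) {
  nm <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
  el <- if (is.null(element)) "  " else sprintf("%2s", element)
  sprintf("%-6s%5d %s%s%3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %s",
          record, serial, nm, altloc, resname, chain, seqid, icode,
          x, y, z, occ, 0, el)
}

# a chain of glycines on a 10-A grid (no contacts anywhere)
gly_chain_lines <- function(chain, seqids, offset = 0) {
  unlist(lapply(seq_along(seqids), function(i) {
    x <- offset + 10 * i
    c(pdb_line(serial = 4 * i - 3, name = "N", resname = "GLY",
               chain = chain, seqid = seqids[i], x = x, y = 0, z = 0),
      pdb_line(serial = 4 * i - 2, name = "CA", resname = "GLY",
               chain = chain, seqid = seqids[i], x = x + 1.5, y = 0, z = 0),
      pdb_line(serial = 4 * i - 1, name = "C", resname = "GLY",
               chain = chain, seqid = seqids[i], x = x + 2.2, y = 1.3, z = 0),
      pdb_line(serial = 4 * i, name = "O", resname = "GLY",
               chain = chain, seqid = seqids[i], x = x + 1.7, y = 2.4, z = 0))
  }))
}

# minimal residue atom table with the attributes getResidue() sets
make_residue <- function(resname, atoms, chain = "A", seqid = 1) {
  df <- data.frame(chain = chain, seqid = seqid, icode = "",
                   resname = resname, kind = "protein",
                   atom = atoms$atom, element = atoms$element,
                   x = atoms$x, y = atoms$y, z = atoms$z,
                   stringsAsFactors = FALSE)
  attr(df, "resname") <- resname
  attr(df, "kind") <- "protein"
  attr(df, "chain") <- chain
  attr(df, "seqid") <- seqid
  attr(df, "icode") <- ""
  df
}
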