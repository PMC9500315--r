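# Abaqus-INP-subset export: *NODE, *ELEMENT, *NSET, *ELSET, *SURFACE.
# Node orderings of C3D10/C3D15 coincide with the VTK orderings used
# internally; tet faces map to S1..S4 by corner-set equality.

INP_TYPE <- c(tet4 = "C3D4", tet10 = "C3D10M", wedge6 = "C3D6",
              wedge15 = "C3D15", truss2 = "T3D2", hex8 = "C3D8")

write_model_inp <- function(x, path) {
  mesh <- if (inherits(x, "spine_model")) x$mesh else x
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("*HEADING")
  w("cervifem synthetic spine export")
  w("*NODE")
  writeLines(sprintf("%d, %.10g, %.10g, %.10g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  off <- 0L
  for (bi in seq_along(mesh$blocks)) {
    b <- mesh$blocks[[bi]]
    if (nrow(b$conn) == 0) next
    w("*ELEMENT, TYPE=%s, ELSET=BLOCK%d", INP_TYPE[[b$kind]], bi)
    ids <- off + seq_len(nrow(b$conn))
    writeLines(paste0(ids, ", ",
                      apply(b$conn, 1, paste, collapse = ", ")), con)
    off <- off + nrow(b$conn)
  }
  wrap16 <- function(v) {
    idx <- split(v, ceiling(seq_along(v) / 16))
    vapply(idx, function(r) paste(r, collapse = ", "), character(1))
  }
  for (nm in names(mesh$nsets)) {
    if (!length(mesh$nsets[[nm]])) next
    w("*NSET, NSET=%s", toupper(gsub("[^A-Za-z0-9_]", "_", nm)))
    writeLines(wrap16(mesh$nsets[[nm]]), con)
  }
  for (nm in names(mesh$elsets)) {
    if (!length(mesh$elsets[[nm]])) next
    w("*ELSET, ELSET=%s", toupper(gsub("[^A-Za-z0-9_]", "_", nm)))
    writeLines(wrap16(mesh$elsets[[nm]]), con)
  }
  for (nm in names(mesh$surfaces)) {
    sf <- mesh$surfaces[[nm]]
    if (!nrow(sf)) next
    safe <- toupper(gsub("[^A-Za-z0-9_]", "_", nm))
    # one elset per face id
    for (f in sort(unique(sf$face))) {
      w("*ELSET, ELSET=_%s_S%d", safe, f)
      writeLines(wrap16(sf$elem[sf$face == f]), con)
    }
    w("*SURFACE, TYPE=ELEMENT, NAME=%s", safe)
    for (f in sort(unique(sf$face)))
      w("_%s_S%d, S%d", safe, f, f)
  }
  invisible(path)
}
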