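# PDB fixed-column slices (1-based, inclusive), per the wwPDB format spec.
pdb_field <- function(lines, from, to) {
  out <- substr(lines, from, to)
  trimws(out)
}

#' Parse a PDB file into protein chains
#'
#' Reads CA atoms from `ATOM` records and secondary-structure annotation from
#' `HELIX`/`SHEET` records. Multi-model files (MD trajectories, NMR) yield one
#' `ProteinChain` per `MODEL` block. When several chains are selected they are
#' concatenated into one track with a segment break recorded at each junction.
#' Alternate locations are resolved by keeping the first occurrence of each
#' residue.
#'
#' @param text PDB file content as a single string or character vector of
#'   lines.
#' @param chain_filter Optional character vector of chain ids to keep
#'   (default: all chains, in order of first appearance).
#' @param source_id Label stored on the resulting chains; multi-model input
#'   gets `"<source_id>#<model>"` per frame.
#' @return List of `ProteinChain`, one per model (length one for ordinary
#'   single-model files).
#' @export
parse_pdb <- function(text, chain_filter = NULL, source_id = "pdb") {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1L]] else text
  rec <- substr(lines, 1L, 6L)

  helix_lines <- lines[startsWith(rec, "HELIX")]
  sheet_lines <- lines[startsWith(rec, "SHEET")]

  # split ATOM/TER lines into models
  model_ids <- integer(0)
  cur_model <- 1L
  seen_model_rec <- FALSE
  atom_lines <- character(0)
  atom_model <- integer(0)
  for (ln in lines) {
    r6 <- substr(ln, 1L, 6L)
    if (startsWith(r6, "MODEL")) {
      seen_model_rec <- TRUE
      id <- suppressWarnings(as.integer(trimws(substr(ln, 11L, 14L))))
      cur_model <- if (is.na(id)) cur_model + 1L else id
      model_ids <- c(model_ids, cur_model)
    } else if (r6 == "ATOM  ") {
      atom_lines <- c(atom_lines, ln)
      atom_model <- c(atom_model, cur_model)
    }
  }
  if (!seen_model_rec) atom_model <- rep(1L, length(atom_lines))
  if (length(atom_lines) == 0L) stop("empty structure: no ATOM records")

  models <- sort(unique(atom_model))
  out <- vector("list", length(models))
  for (mi in seq_along(models)) {
    ml <- atom_lines[atom_model == models[mi]]
    sid <- if (length(models) > 1L) paste0(source_id, "#", models[mi]) else source_id
    out[[mi]] <- parse_pdb_model(ml, helix_lines, sheet_lines, chain_filter, sid)
  }
  out
}

parse_pdb_model <- function(atom_lines, helix_lines, sheet_lines,
                            chain_filter, source_id) {
  name <- pdb_field(atom_lines, 13L, 16L)
  keep <- name == "CA"
  atom_lines <- atom_lines[keep]
  if (length(atom_lines) == 0L) stop("empty structure: no CA atoms")

  altloc <- substr(atom_lines, 17L, 17L)
  resname <- pdb_field(atom_lines, 18L, 20L)
  chain <- substr(atom_lines, 22L, 22L)
  resseq <- pdb_field(atom_lines, 23L, 26L)
  icode <- trimws(substr(atom_lines, 27L, 27L))
  x <- as.numeric(substr(atom_lines, 31L, 38L))
  y <- as.numeric(substr(atom_lines, 39L, 46L))
  z <- as.numeric(substr(atom_lines, 47L, 54L))

  res_key <- paste0(chain, ":", resseq, icode)
  first <- !duplicated(res_key)          # first altloc wins
  df <- data.frame(chain = chain[first],
                   res_id = paste0(resseq, icode)[first],
                   name = resname[first],
                   x = x[first], y = y[first], z = z[first],
                   key = res_key[first],
                   stringsAsFactors = FALSE)

  chains_present <- unique(df$chain)
  sel <- if (is.null(chain_filter)) chains_present else {
    missing <- setdiff(chain_filter, chains_present)
    if (length(missing)) {
      stop("requested chain(s) not present: ", paste(missing, collapse = ", "))
    }
    chains_present[chains_present %in% chain_filter]
  }
  df <- df[df$chain %in% sel, , drop = FALSE]
  if (nrow(df) == 0L) stop("empty structure: no CA atoms in selected chains")
  # preserve file order inside each chain, chains in order of appearance
  df <- df[order(match(df$chain, sel)), , drop = FALSE]
  rownames(df) <- NULL

  breaks <- which(df$chain[-1L] != df$chain[-nrow(df)])
  key_to_idx <- stats::setNames(seq_len(nrow(df)) - 1L, df$key)

  sses <- rbind(parse_ss_records(helix_lines, "HELIX", key_to_idx),
                parse_ss_records(sheet_lines, "SHEET", key_to_idx))

  protein_chain(source_id = source_id,
                chain_id = paste(sel, collapse = "+"),
                residues = df[, c("res_id", "name", "chain")],
                ca = as.matrix(df[, c("x", "y", "z")]),
                sses = sses,
                segment_breaks = breaks)
}

# Convert HELIX/SHEET records into 0-based [start,end] SSE rows, clipping
# ranges that extend beyond the residues actually present in ATOM records.
parse_ss_records <- function(lines, kind, key_to_idx) {
  if (length(lines) == 0L) return(NULL)
  cols <- if (kind == "HELIX") {
    list(c1 = 20L, s1 = c(22L, 25L), i1 = 26L, c2 = 32L, s2 = c(34L, 37L), i2 = 38L)
  } else {
    list(c1 = 22L, s1 = c(23L, 26L), i1 = 27L, c2 = 33L, s2 = c(34L, 37L), i2 = 38L)
  }
  out <- list()
  nres <- length(key_to_idx)
  keys <- names(key_to_idx)
  for (ln in lines) {
    ch1 <- substr(ln, cols$c1, cols$c1)
    ch2 <- substr(ln, cols$c2, cols$c2)
    k1 <- paste0(ch1, ":", trimws(substr(ln, cols$s1[1L], cols$s1[2L])),
                 trimws(substr(ln, cols$i1, cols$i1)))
    k2 <- paste0(ch2, ":", trimws(substr(ln, cols$s2[1L], cols$s2[2L])),
                 trimws(substr(ln, cols$i2, cols$i2)))
    a <- key_to_idx[k1]
    b <- key_to_idx[k2]
    if (is.na(a) || is.na(b)) {
      # clip to the residues present on the same chain
      on_chain <- which(startsWith(keys, paste0(ch1, ":")))
      if (is.na(a)) a <- if (length(on_chain)) key_to_idx[on_chain[1L]] else NA
      if (is.na(b)) b <- if (length(on_chain)) key_to_idx[on_chain[length(on_chain)]] else NA
      if (is.na(a) || is.na(b) || a > b) {
        warning(kind, " record references residues absent from ATOM records; dropped")
        next
      }
      warning(kind, " record clipped to available residue range")
    }
    if (a > b) next
    out[[length(out) + 1L]] <- data.frame(kind = kind, start = a, end = b,
                                          stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

#' Serialize chains to minimal PDB text
#'
#' Writes CA-only `ATOM` records plus `HELIX`/`SHEET` records for the chain's
#' bead elements; a list of chains with identical residue numbering is
#' written as a multi-`MODEL` trajectory. Round-trips through [parse_pdb()].
#'
#' @param chains A `ProteinChain`, a list of them, or a `Trajectory`.
#' @return PDB text (single string).
#' @export
write_pdb <- function(chains) {
  if (inherits(chains, "ProteinChain")) chains <- list(chains)
  if (inherits(chains, "Trajectory")) chains <- chains$frames
  multi <- length(chains) > 1L
  out <- character(0)

  # SSE records from the first frame define the annotation
  first <- chains[[1L]]
  beads <- chain_beads(first)
  hi <- 0L; si <- 0L
  for (k in seq_len(nrow(beads))) {
    a <- beads$start[k] + 1L
    b <- beads$end[k] + 1L
    r1 <- first$residues[a, ]
    r2 <- first$residues[b, ]
    n1 <- suppressWarnings(as.integer(gsub("[^0-9-]", "", r1$res_id)))
    n2 <- suppressWarnings(as.integer(gsub("[^0-9-]", "", r2$res_id)))
    if (beads$kind[k] == "HELIX") {
      hi <- hi + 1L
      out <- c(out, sprintf(
        "HELIX  %3d %3s %3s %1s %4d  %3s %1s %4d  1%30s%6d",
        hi, sprintf("H%02d", hi), r1$name, r1$chain, n1,
        r2$name, r2$chain, n2, "", b - a + 1L))
    } else {
      si <- si + 1L
      out <- c(out, sprintf(
        "SHEET  %3d %3s 1 %3s %1s%4d  %3s %1s%4d  0",
        si, sprintf("S%02d", si), r1$name, r1$chain, n1,
        r2$name, r2$chain, n2))
    }
  }

  for (f in seq_along(chains)) {
    ch <- chains[[f]]
    if (multi) out <- c(out, sprintf("MODEL     %4d", f))
    serial <- 0L
    for (i in seq_len(n_residues(ch))) {
      serial <- serial + 1L
      num <- suppressWarnings(as.integer(gsub("[^0-9-]", "", ch$residues$res_id[i])))
      ic <- gsub("[0-9-]", "", ch$residues$res_id[i])
      if (!nzchar(ic)) ic <- " "
      out <- c(out, sprintf(
        "ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, ch$residues$name[i], ch$residues$chain[i], num, ic,
        ch$ca[i, 1L], ch$ca[i, 2L], ch$ca[i, 3L]))
    }
    if (multi) out <- c(out, "ENDMDL")
  }
  paste0(paste(out, collapse = "\n"), "\nEND\n")
}

#' Parse classic DSSP output into an SSE tiling
#'
#' Consumes the per-residue table of a DSSP run and maps the eight DSSP
#' states onto the three glyph kinds: `H`, `G`, `I` become `HELIX`; `E`, `B`
#' become `SHEET`; everything else (`T`, `S`, blank, ...) becomes `COIL`.
#' Consecutive residues of equal kind are merged into runs, and the result
#' tiles the chain completely. This three-state collapse is a conventional
#' choice, not dictated by the method itself.
#'
#' @param text DSSP file content (string or lines).
#' @param chain `ProteinChain` whose residues the DSSP rows are matched
#'   against (by chain id + author residue number + insertion code).
#' @return `data.frame` of SSEs tiling the chain (same shape as
#'   `chain$sses`).
#' @export
parse_dssp <- function(text, chain) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1L]] else text
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0L) stop("not a DSSP file: residue table header missing")
  body <- lines[(hdr[1L] + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  aa <- substr(body, 14L, 14L)
  body <- body[aa != "!"]                 # chain-break rows
  resnum <- trimws(substr(body, 6L, 10L))
  icode <- trimws(substr(body, 11L, 11L))
  dchain <- substr(body, 12L, 12L)
  code <- substr(body, 17L, 17L)
  key <- paste0(dchain, ":", resnum, icode)

  chain_key <- paste0(chain$residues$chain, ":", chain$residues$res_id)
  idx <- match(chain_key, key)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop("residue ", chain_key[bad], " not found in DSSP output")
  }
  kinds <- dssp_kind(code[idx])
  retile_chain(chain, kinds)$sses
}

# Three-state collapse of DSSP one-letter codes.
dssp_kind <- function(code) {
  out <- rep("COIL", length(code))
  out[code %in% c("H", "G", "I")] <- "HELIX"
  out[code %in% c("E", "B")] <- "SHEET"
  out
}

#' Apply an SSE tiling derived from per-residue codes
#'
#' Convenience used by tests and the DSSP reader: takes a per-residue vector
#' of DSSP-style one-letter codes (or kind names) and re-tiles the chain.
#'
#' @param chain A `ProteinChain`.
#' @param codes Character vector, one element per residue: either DSSP codes
#'   (`"H"`, `"E"`, `"C"`, ...) or kind names.
#' @return The chain with a new SSE tiling.
#' @export
assign_sses <- function(chain, codes) {
  if (length(codes) == 1L && nchar(codes) > 1L) {
    codes <- strsplit(codes, "", fixed = TRUE)[[1L]]
  }
  if (length(codes) != n_residues(chain)) {
    stop("need one code per residue (", n_residues(chain), ")")
  }
  kinds <- ifelse(codes %in% SSE_KINDS, codes, dssp_kind(codes))
  retile_chain(chain, kinds)
}

#' Chain JSON serialization
#'
#' Self-describing JSON format used for fixtures and the `--scene-json`
#' style exports: `{source_id, chain_id, residues: [{res_id, name, chain,
#' ca:[x,y,z]}], sses: [{sse_id, kind, start, end}], segment_breaks: [...]}`.
#' `json_to_chain(chain_to_json(x))` is the identity.
#'
#' @param chain A `ProteinChain`.
#' @return `chain_to_json`: JSON text; `json_to_chain`: a `ProteinChain`.
#' @export
chain_to_json <- function(chain) {
  res <- lapply(seq_len(n_residues(chain)), function(i) {
    list(res_id = chain$residues$res_id[i],
         name = chain$residues$name[i],
         chain = chain$residues$chain[i],
         ca = as.numeric(chain$ca[i, ]))
  })
  sses <- lapply(seq_len(nrow(chain$sses)), function(k) {
    list(sse_id = chain$sses$sse_id[k], kind = chain$sses$kind[k],
         start = chain$sses$start[k], end = chain$sses$end[k])
  })
  jsonlite::toJSON(
    list(source_id = chain$source_id, chain_id = chain$chain_id,
         residues = res, sses = sses,
         segment_breaks = as.integer(chain$segment_breaks)),
    auto_unbox = TRUE, digits = NA)
}

#' @rdname chain_to_json
#' @param text JSON text produced by `chain_to_json` (or hand-written to the
#'   same schema).
#' @export
json_to_chain <- function(text) {
  obj <- jsonlite::fromJSON(text, simplifyDataFrame = TRUE, simplifyVector = TRUE)
  for (field in c("source_id", "chain_id", "residues")) {
    if (is.null(obj[[field]])) stop("invalid chain JSON: missing $", field)
  }
  res <- obj$residues
  if (is.null(res$res_id) || is.null(res$ca)) {
    stop("invalid chain JSON: $residues rows need res_id and ca")
  }
  ca <- if (is.list(res$ca)) do.call(rbind, res$ca) else res$ca
  if (!is.matrix(ca)) ca <- matrix(ca, ncol = 3L, byrow = TRUE)
  if (ncol(ca) != 3L) stop("invalid chain JSON: $residues[].ca must have 3 components")
  sses <- obj$sses
  if (!is.null(sses) && nrow(as.data.frame(sses)) > 0L) {
    sses <- as.data.frame(sses, stringsAsFactors = FALSE)
    if (is.null(sses$kind) || is.null(sses$start) || is.null(sses$end)) {
      stop("invalid chain JSON: $sses rows need kind/start/end")
    }
  } else sses <- NULL
  tryCatch(
    protein_chain(source_id = obj$source_id, chain_id = obj$chain_id,
                  residues = data.frame(
                    res_id = res$res_id,
                    name = if (is.null(res$name)) "ALA" else res$name,
                    chain = if (is.null(res$chain)) obj$chain_id else res$chain,
                    stringsAsFactors = FALSE),
                  ca = ca, sses = sses,
                  segment_breaks = obj$segment_breaks %||% integer()),
    error = function(e) stop("invalid chain JSON: $sses: ", conditionMessage(e),
                             call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
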