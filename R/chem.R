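# Chemistry layer: SMILES standardization, molecular graphs, descriptors and
# fingerprints. Parsing and property calculation are delegated to OpenBabel
# (obabel CLI and ChemmineOB) and ChemmineR; results are memoized per
# canonical SMILES because cohorts re-use a closed fragment vocabulary.

.chemCache <- new.env(parent = emptyenv())

.cacheGet <- function(kind, keys) {
  env <- .chemCache
  full <- paste0(kind, "\r", keys)
  hit <- vapply(full, function(k) exists(k, envir = env, inherits = FALSE), logical(1))
  vals <- vector("list", length(keys))
  vals[hit] <- lapply(full[hit], get, envir = env)
  list(hit = hit, vals = vals)
}

.cacheSet <- function(kind, keys, vals) {
  env <- .chemCache
  full <- paste0(kind, "\r", keys)
  for (i in seq_along(keys)) assign(full[i], vals[[i]], envir = env)
  invisible(NULL)
}

.obabelPath <- function() {
  p <- Sys.which("obabel")
  stopIfNot(nzchar(p), "the 'obabel' executable is required but was not found on the PATH")
  p
}

# Run obabel over a batch of SMILES. Returns raw output lines; molecules that
# fail to parse are silently absent from the output, so callers match records
# back by the per-line title (an index).
.obabelRun <- function(smiles, args) {
  inp <- tempfile(fileext = ".smi")
  out <- tempfile(fileext = ".txt")
  on.exit(unlink(c(inp, out)), add = TRUE)
  writeLines(paste(smiles, seq_along(smiles)), inp)
  res <- suppressWarnings(system2(.obabelPath(), c(inp, args, "-O", out),
                                  stdout = FALSE, stderr = FALSE))
  if (!file.exists(out)) return(character(0))
  readLines(out, warn = FALSE)
}

#' Standardize structure line notation
#'
#' Applies the standard small-molecule cleaning sequence: the largest
#' covalently connected fragment is retained (salt and counter-ion removal),
#' ionized groups are neutralized where a proton can be added or removed, and
#' the canonical SMILES form is returned. The operation is idempotent:
#' standardizing an already standardized string returns it unchanged.
#'
#' @param smiles character vector of SMILES strings.
#' @return A character vector of canonical SMILES, `NA` where the input could
#'   not be parsed (a warning lists the offending positions).
#' @examples
#' standardizeStructure(c("OC(=O)c1ccccc1.[Na+]", "C[NH+]1CCCCC1"))
#' @export
standardizeStructure <- function(smiles) {
  smiles <- as.character(smiles)
  out <- rep(NA_character_, length(smiles))
  if (length(smiles) == 0) return(out)
  cached <- .cacheGet("std", smiles)
  out[cached$hit] <- unlist(cached$vals[cached$hit], use.names = FALSE)
  todo <- which(!cached$hit & !is.na(smiles) & nzchar(smiles))
  if (length(todo)) {
    lines <- .obabelRun(smiles[todo], c("-ocan", "-r", "--neutralize"))
    if (length(lines)) {
      parts <- strsplit(lines, "\t", fixed = TRUE)
      ok <- lengths(parts) == 2L
      idx <- as.integer(vapply(parts[ok], `[`, "", 2L))
      out[todo[idx]] <- vapply(parts[ok], `[`, "", 1L)
    }
    .cacheSet("std", smiles[todo], as.list(out[todo]))
  }
  bad <- which(!is.na(smiles) & nzchar(smiles) & is.na(out))
  if (length(bad)) {
    warning(sprintf("%d structure(s) could not be parsed and were flagged NA (positions: %s)",
                    length(bad), paste(utils::head(bad, 10), collapse = ", ")))
  }
  out
}

# Parse SMILES into ChemmineR SDF objects (one obabel-backed batch call, with
# a per-molecule fallback so one bad string does not sink the batch).
.parseMols <- function(smiles) {
  out <- vector("list", length(smiles))
  cached <- .cacheGet("sdf", smiles)
  out[cached$hit] <- cached$vals[cached$hit]
  todo <- which(!cached$hit)
  if (length(todo)) {
    sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles[todo])),
                    error = function(e) NULL)
    parsed <- if (!is.null(sdf) && length(sdf) == length(todo)) {
      suppressWarnings(ChemmineR::cid(sdf) <- paste0("m", seq_along(sdf)))
      valid <- ChemmineR::validSDF(sdf)
      lapply(seq_along(todo), function(i) if (valid[i]) sdf[[i]] else NULL)
    } else {
      lapply(smiles[todo], function(s) {
        one <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(s)), error = function(e) NULL)
        if (is.null(one) || length(one) != 1) return(NULL)
        suppressWarnings(ChemmineR::cid(one) <- "m1")
        if (ChemmineR::validSDF(one)[1]) one[[1]] else NULL
      })
    }
    out[todo] <- parsed
    .cacheSet("sdf", smiles[todo], parsed)
  }
  out
}

.HALOGENS <- c("F", "Cl", "Br", "I")
.DEFAULT_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1, I = 1, B = 3, Si = 4)

# Molecular graph with derived per-atom annotations used by the FCFP
# fingerprint, the sp3 fraction and the Murcko scaffold pruning.
.molGraph <- function(mol) {
  ab <- ChemmineR::atomblock(mol)
  bb <- ChemmineR::bondblock(mol)
  elements <- gsub("_.*", "", rownames(ab))
  n <- length(elements)
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) {
    matrix(integer(0), ncol = 3)
  } else {
    cbind(as.integer(bb[, 1]), as.integer(bb[, 2]), as.integer(bb[, 3]))
  }
  deg <- tabulate(c(bonds[, 1], bonds[, 2]), nbins = n)
  bondsum <- numeric(n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      bondsum[bonds[k, 1]] <- bondsum[bonds[k, 1]] + bonds[k, 3]
      bondsum[bonds[k, 2]] <- bondsum[bonds[k, 2]] + bonds[k, 3]
    }
  }
  defv <- .DEFAULT_VALENCE[elements]
  defv[is.na(defv)] <- 0
  nH <- pmax(0, defv - bondsum)
  aromatic <- rep(FALSE, n)
  ringAtom <- rep(FALSE, n)
  rng <- tryCatch(
    suppressWarnings(ChemmineR::rings(mol, upper = 12, type = "all", arom = TRUE)),
    error = function(e) NULL)
  if (!is.null(rng) && length(rng$RINGS)) {
    for (i in seq_along(rng$RINGS)) {
      ids <- as.integer(gsub(".*_", "", rng$RINGS[[i]]))
      ringAtom[ids] <- TRUE
      if (isTRUE(rng$AROMATIC[i])) aromatic[ids] <- TRUE
    }
  }
  list(elements = elements, bonds = bonds, degree = deg, nH = nH,
       aromatic = aromatic, ringAtom = ringAtom, n = n)
}

# Adjacency list (neighbour index + bond order) from a graph.
.adjacency <- function(g) {
  adj <- vector("list", g$n)
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      i <- g$bonds[k, 1]; j <- g$bonds[k, 2]; o <- g$bonds[k, 3]
      adj[[i]] <- rbind(adj[[i]], c(j, o))
      adj[[j]] <- rbind(adj[[j]], c(i, o))
    }
  }
  adj
}

# ---- physicochemical descriptors ------------------------------------------

.parseFormula <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)
  toks <- regmatches(formula, m)
  lapply(toks, function(tk) {
    el <- gsub("[0-9]", "", tk)
    ct <- as.integer(gsub("[^0-9]", "", tk))
    ct[is.na(ct)] <- 1L
    stats::setNames(ct, el)
  })
}

.ROTOR_SMARTS <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

.PHYSCHEM_NAMES <- c("logP", "TPSA", "MW", "RotatableBonds", "HBondDonors",
                     "HBondAcceptors", "Heteroatoms", "Atoms", "HeavyAtoms",
                     "Stereocenters", "FractionCsp3")

.EXTRA_DESC_NAMES <- c("MR", "Rings", "AromaticRings", "AromaticAtoms", "RingAtoms",
                       "NitrogenAtoms", "OxygenAtoms", "SulfurAtoms", "HalogenAtoms",
                       "Bonds", "BasicNitrogens", "AcidicGroups", "AmideBonds",
                       "FractionHeteroatoms", "MeanAtomicMass")

# 11 core physicochemical descriptors (plus the 15 extended chemical-space
# descriptors when extended = TRUE), one row per input structure. Rows for
# unparseable structures are NA.
.physchem <- function(smiles, extended = FALSE) {
  kind <- if (extended) "pc26" else "pc11"
  nmz <- if (extended) c(.PHYSCHEM_NAMES, .EXTRA_DESC_NAMES) else .PHYSCHEM_NAMES
  out <- matrix(NA_real_, nrow = length(smiles), ncol = length(nmz),
                dimnames = list(NULL, nmz))
  cached <- .cacheGet(kind, smiles)
  for (i in which(cached$hit)) out[i, ] <- cached$vals[[i]]
  todo <- which(!cached$hit)
  if (length(todo)) {
    mols <- .parseMols(smiles[todo])
    okm <- !vapply(mols, is.null, logical(1))
    if (any(okm)) {
      sub <- todo[okm]
      sdfset <- methods::new("SDFset", SDF = mols[okm], ID = paste0("m", seq_along(sub)))
      p <- ChemmineR::propOB(sdfset)
      rot <- ChemmineR::smartsSearchOB(sdfset, .ROTOR_SMARTS, uniqueMatches = FALSE)
      counts <- .parseFormula(p$formula)
      graphs <- lapply(mols[okm], .molGraph)
      for (k in seq_along(sub)) {
        g <- graphs[[k]]
        fc <- counts[[k]]
        atoms <- sum(fc)
        heavy <- g$n
        hetero <- sum(!(g$elements %in% c("C", "H")))
        stereo <- lengths(regmatches(p$cansmi[k], gregexpr("[@]+", p$cansmi[k])))
        nC <- sum(g$elements == "C")
        sp3 <- 0
        if (nC > 0) {
          single <- rep(TRUE, g$n)
          if (nrow(g$bonds)) {
            multi <- g$bonds[g$bonds[, 3] > 1, , drop = FALSE]
            single[c(multi[, 1], multi[, 2])] <- FALSE
          }
          single[g$aromatic] <- FALSE
          sp3 <- sum(single & g$elements == "C") / nC
        }
        row <- c(p$logP[k], p$TPSA[k], p$MW[k], rot[k], p$HBD[k], p$HBA1[k],
                 hetero, atoms, heavy, stereo, sp3)
        if (extended) {
          nb <- nrow(g$bonds)
          rngInfo <- .ringCounts(mols[okm][[k]], g)
          basicN <- .basicNitrogens(g)
          acid <- .acidicGroups(g)
          amide <- .amideBonds(g)
          row <- c(row,
                   p$MR[k], rngInfo["rings"], rngInfo["aromaticRings"],
                   sum(g$aromatic), sum(g$ringAtom),
                   sum(g$elements == "N"), sum(g$elements == "O"),
                   sum(g$elements == "S"), sum(g$elements %in% .HALOGENS),
                   nb, basicN, acid, amide, hetero / max(heavy, 1),
                   p$MW[k] / max(atoms, 1))
        }
        out[sub[k], ] <- row
      }
    }
    .cacheSet(kind, smiles[todo], lapply(todo, function(i) out[i, ]))
  }
  out
}

.ringCounts <- function(mol, g) {
  rng <- tryCatch(
    suppressWarnings(ChemmineR::rings(mol, upper = 12, type = "all", arom = TRUE)),
    error = function(e) NULL)
  if (is.null(rng)) return(c(rings = 0, aromaticRings = 0))
  c(rings = length(rng$RINGS), aromaticRings = sum(rng$AROMATIC))
}

# Basic nitrogen: non-aromatic N not adjacent to a carbonyl carbon.
.basicNitrogens <- function(g) {
  if (!any(g$elements == "N")) return(0)
  adj <- .adjacency(g)
  carbonylC <- rep(FALSE, g$n)
  if (nrow(g$bonds)) {
    dbl <- g$bonds[g$bonds[, 3] == 2, , drop = FALSE]
    for (k in seq_len(nrow(dbl))) {
      i <- dbl[k, 1]; j <- dbl[k, 2]
      if (g$elements[i] == "C" && g$elements[j] %in% c("O", "S")) carbonylC[i] <- TRUE
      if (g$elements[j] == "C" && g$elements[i] %in% c("O", "S")) carbonylC[j] <- TRUE
    }
  }
  sum(vapply(which(g$elements == "N" & !g$aromatic), function(i) {
    nb <- adj[[i]]
    if (is.null(nb)) return(TRUE)
    if (any(nb[, 2] > 1)) return(FALSE)              # imine/nitrile N
    !any(carbonylC[nb[, 1]])                         # amide/sulfonamide N
  }, logical(1)))
}

# Acidic group: O-H bound to a carbonyl or sulfonyl centre.
.acidicGroups <- function(g) {
  adj <- .adjacency(g)
  sum(vapply(seq_len(g$n), function(i) {
    if (g$elements[i] != "O" || g$nH[i] < 1) return(FALSE)
    nb <- adj[[i]]
    if (is.null(nb)) return(FALSE)
    any(vapply(nb[, 1], function(j) {
      if (!g$elements[j] %in% c("C", "S")) return(FALSE)
      jn <- adj[[j]]
      any(jn[, 2] == 2 & g$elements[jn[, 1]] == "O")
    }, logical(1)))
  }, logical(1)))
}

.amideBonds <- function(g) {
  if (!nrow(g$bonds)) return(0)
  adj <- .adjacency(g)
  cnt <- 0
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds[k, 1]; j <- g$bonds[k, 2]
    if (g$bonds[k, 3] != 1) next
    for (pair in list(c(i, j), c(j, i))) {
      a <- pair[1]; b <- pair[2]
      if (g$elements[a] == "C" && g$elements[b] == "N") {
        an <- adj[[a]]
        if (!is.null(an) && any(an[, 2] == 2 & g$elements[an[, 1]] == "O")) cnt <- cnt + 1
      }
    }
  }
  cnt
}

# ---- fingerprints ----------------------------------------------------------

.HEXBIT <- local({
  m <- matrix(0L, nrow = 16, ncol = 4)
  for (v in 0:15) m[v + 1, ] <- as.integer(bitwAnd(bitwShiftR(v, 3:0), 1L))
  rownames(m) <- c(0:9, letters[1:6])
  m
})

# ECFP6 via obabel's ECFP implementation (4096-bit), folded to nbits by OR.
.ecfp <- function(smiles, nbits = 1024L) {
  out <- matrix(NA_integer_, nrow = length(smiles), ncol = nbits)
  cached <- .cacheGet(paste0("ecfp", nbits), smiles)
  for (i in which(cached$hit)) out[i, ] <- cached$vals[[i]]
  todo <- which(!cached$hit)
  if (length(todo)) {
    lines <- .obabelRun(smiles[todo], c("-ofpt", "-xfECFP6", "-xh"))
    if (length(lines)) {
      hdr <- grepl("^>", lines)
      rec <- cumsum(hdr)
      titles <- as.integer(sub("^>\\s*(\\S+).*", "\\1", lines[hdr]))
      hexline <- !hdr & grepl("^[0-9a-fA-F ]+$", lines)  # skip annotation lines
      for (r in seq_along(titles)) {
        hex <- paste(lines[hexline & rec == r], collapse = " ")
        hex <- tolower(gsub("[^0-9a-fA-F]", "", hex))
        ch <- strsplit(hex, "", fixed = TRUE)[[1]]
        if ((4L * length(ch)) %% nbits != 0) next    # malformed record
        bits <- as.vector(t(.HEXBIT[ch, , drop = FALSE]))
        # obabel prints 32-bit words most-significant nibble first; bit order
        # within a record only needs to be consistent, which this is.
        folded <- as.integer(colSums(matrix(bits, ncol = nbits, byrow = TRUE)) > 0)
        out[todo[titles[r]], ] <- folded
      }
    }
    .cacheSet(paste0("ecfp", nbits), smiles[todo], lapply(todo, function(i) out[i, ]))
  }
  out
}

# Functional-class circular fingerprint (FCFP-like): Morgan iteration to the
# given radius over atom invariants that encode pharmacophoric roles rather
# than element identity, hashed into nbits buckets.
.FCFP_MOD <- 2147483647

.hashPair <- function(a, b) (a * 31 + b) %% .FCFP_MOD

.fcfpOne <- function(g, radius = 3L, nbits = 1024L) {
  if (g$n == 0) return(integer(nbits))
  adj <- .adjacency(g)
  donor <- g$elements %in% c("N", "O") & g$nH >= 1
  acceptor <- g$elements %in% c("N", "O")
  halogen <- g$elements %in% .HALOGENS
  carbonylC <- rep(FALSE, g$n)
  if (nrow(g$bonds)) {
    dbl <- g$bonds[g$bonds[, 3] == 2, , drop = FALSE]
    for (k in seq_len(nrow(dbl))) {
      i <- dbl[k, 1]; j <- dbl[k, 2]
      if (g$elements[i] == "C" && g$elements[j] == "O") carbonylC[i] <- TRUE
      if (g$elements[j] == "C" && g$elements[i] == "O") carbonylC[j] <- TRUE
    }
  }
  basic <- vapply(seq_len(g$n), function(i) {
    if (g$elements[i] != "N" || g$aromatic[i]) return(FALSE)
    nb <- adj[[i]]
    if (is.null(nb)) return(TRUE)
    all(nb[, 2] == 1) && !any(carbonylC[nb[, 1]])
  }, logical(1))
  acidic <- vapply(seq_len(g$n), function(i) {
    if (g$elements[i] != "O" || g$nH[i] < 1) return(FALSE)
    nb <- adj[[i]]
    !is.null(nb) && any(carbonylC[nb[, 1]])
  }, logical(1))
  inv <- (donor * 32 + acceptor * 16 + basic * 8 + acidic * 4 +
            g$aromatic * 2 + halogen) + 64
  ids <- as.numeric(inv)
  all_ids <- ids
  for (r in seq_len(radius)) {
    new_ids <- ids
    for (i in seq_len(g$n)) {
      nb <- adj[[i]]
      h <- .hashPair(r, ids[i])
      if (!is.null(nb)) {
        env <- nb[, 2] * .FCFP_MOD / 8 + ids[nb[, 1]]
        for (e in sort(env)) h <- .hashPair(h, e %% .FCFP_MOD)
      }
      new_ids[i] <- h
    }
    ids <- new_ids
    all_ids <- c(all_ids, ids)
  }
  bits <- integer(nbits)
  bits[(all_ids %% nbits) + 1] <- 1L
  bits
}

.fcfp <- function(smiles, nbits = 1024L, radius = 3L) {
  out <- matrix(NA_integer_, nrow = length(smiles), ncol = nbits)
  key <- paste0("fcfp", nbits, ".", radius)
  cached <- .cacheGet(key, smiles)
  for (i in which(cached$hit)) out[i, ] <- cached$vals[[i]]
  todo <- which(!cached$hit)
  if (length(todo)) {
    mols <- .parseMols(smiles[todo])
    for (k in seq_along(todo)) {
      if (is.null(mols[[k]])) next
      out[todo[k], ] <- .fcfpOne(.molGraph(mols[[k]]), radius = radius, nbits = nbits)
    }
    .cacheSet(key, smiles[todo], lapply(todo, function(i) out[i, ]))
  }
  out
}

# ---- Murcko scaffold -------------------------------------------------------

# Bemis-Murcko framework: iteratively remove terminal (degree-1) atoms so only
# ring systems and the linkers between them remain. Returns the canonical
# SMILES of the framework, or NA for acyclic molecules.
.murckoScaffold <- function(smiles) {
  out <- rep(NA_character_, length(smiles))
  cached <- .cacheGet("murcko", smiles)
  out[cached$hit] <- unlist(cached$vals[cached$hit], use.names = FALSE)
  todo <- which(!cached$hit)
  if (length(todo)) {
    mols <- .parseMols(smiles[todo])
    raw <- rep(NA_character_, length(todo))
    for (k in seq_along(todo)) {
      mol <- mols[[k]]
      if (is.null(mol)) next
      g <- .molGraph(mol)
      keep <- rep(TRUE, g$n)
      repeat {
        deg <- tabulate(c(g$bonds[keep[g$bonds[, 1]] & keep[g$bonds[, 2]], 1],
                          g$bonds[keep[g$bonds[, 1]] & keep[g$bonds[, 2]], 2]),
                        nbins = g$n)
        drop <- keep & deg <= 1 & !g$ringAtom
        if (!any(drop)) break
        keep[drop] <- FALSE
      }
      if (!any(keep & g$ringAtom)) next  # acyclic
      sub <- ChemmineR::atomsubset(mol, atomrows = which(keep))
      smi <- tryCatch(
        as.character(suppressWarnings(ChemmineR::sdf2smiles(methods::as(sub, "SDFset")))),
        error = function(e) NA_character_)
      raw[k] <- smi
    }
    canon <- rep(NA_character_, length(todo))
    has <- which(!is.na(raw))
    if (length(has)) canon[has] <- .canonicalPlain(raw[has])
    out[todo] <- canon
    .cacheSet("murcko", smiles[todo], as.list(canon))
  }
  out
}

# Canonical SMILES without salt stripping/neutralization.
.canonicalPlain <- function(smiles) {
  out <- rep(NA_character_, length(smiles))
  lines <- .obabelRun(smiles, "-ocan")
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ok <- lengths(parts) == 2L
    idx <- as.integer(vapply(parts[ok], `[`, "", 2L))
    out[idx] <- vapply(parts[ok], `[`, "", 1L)
  }
  out
}
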