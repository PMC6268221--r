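#' Pyranose residue
#'
#' A single pyranose unit of an oligosaccharide. Supported monomers are
#' D-glucose, D-galactose, D-mannose (hexoses) and L-rhamnose, L-fucose
#' (6-deoxy sugars; their C6 is a methyl carbon resonating near 16-18 ppm).
#' A residue may carry a 2-acetamido group (`n_acetylated = TRUE`, adding a
#' carbonyl and a methyl carbon) and O-methyl groups on ring positions;
#' position 1 (the anomeric oxygen) is only methylatable on the reducing end,
#' where it locks the anomeric configuration (no mutarotation).
#'
#' @param monomer One of `"Glc"`, `"Gal"`, `"Man"`, `"Rha"`, `"Fuc"`.
#' @param anomer `"alpha"` or `"beta"`. For a glycosyl donor this is the
#'   configuration of its glycosidic bond; for the reducing end it is the
#'   reducing anomeric configuration.
#' @param n_acetylated Logical; 2-acetamido substitution (only meaningful for
#'   amino-sugar derivatives of Glc/Gal/Man).
#' @param o_methyl Integer vector of O-methylated positions, a subset of
#'   `c(1, 2, 3, 4, 6)`.
#' @return An object of class `glyco_residue`.
#' @examples
#' residue("Glc", "beta", n_acetylated = TRUE)
#' @export
residue <- function(monomer, anomer, n_acetylated = FALSE, o_methyl = integer()) {
  if (!monomer %in% monomers) {
    abort(paste0("unknown monomer '", monomer, "'; expected one of ",
                 paste(monomers, collapse = ", ")), class = "glyco_domain_error")
  }
  if (!anomer %in% c("alpha", "beta")) {
    abort("anomer must be 'alpha' or 'beta'", class = "glyco_domain_error")
  }
  o_methyl <- sort(unique(as.integer(o_methyl)))
  if (!all(o_methyl %in% c(1L, 2L, 3L, 4L, 6L))) {
    abort("o_methyl positions must lie in {1,2,3,4,6}", class = "glyco_domain_error")
  }
  if (isTRUE(n_acetylated) && 2L %in% o_methyl) {
    abort("position 2 carries the N-acetyl group and cannot be O-methylated",
          class = "glyco_domain_error")
  }
  if (isTRUE(n_acetylated) && monomer %in% deoxy_monomers) {
    abort("N-acetylation is only supported on hexose residues (Glc, Gal, Man)",
          class = "glyco_domain_error")
  }
  structure(
    list(monomer = monomer, anomer = anomer,
         n_acetylated = isTRUE(n_acetylated), o_methyl = o_methyl),
    class = "glyco_residue"
  )
}

# enantiomer prefix implied by the monomer (Rha and Fuc occur as L sugars)
monomer_dl <- function(m) if (m %in% deoxy_monomers) "L" else "D"

#' Di- or trisaccharide structure
#'
#' Assembles residues and glycosidic linkages into a validated structure.
#' Residue index 1 is always the reducing end. A disaccharide has one linkage;
#' a trisaccharide has two and is either linear (first -> middle -> reducing)
#' or branched (both donors attached to the reducing end at distinct
#' positions). For branched structures the two branches are canonicalized in
#' ascending order of linkage position: the lower-position branch is the
#' "first" residue/linkage, the higher-position one the "second" (middle).
#'
#' @param residues List of [residue()] objects; element 1 is the reducing end,
#'   elements 2..3 are donors ordered non-reducing-first (see Details).
#' @param linkages List of one or two linkages, each a list with fields
#'   `donor` (residue index), `acceptor` (residue index) and `position`
#'   (2, 3, 4 or 6, the acceptor carbon). The linkage anomer is the donor
#'   residue's `anomer`.
#' @return An object of class `oligo_structure` with fields `residues`,
#'   `linkages` (canonically ordered: first linkage before second), `chain`
#'   (`"linear"`, `"branched"` or `"not_applicable"` for disaccharides) and
#'   `reducing_anomer`.
#' @details For a linear trisaccharide residue 3 is the first residue (the
#'   one farthest from the reducing end) and residue 2 the middle one, with
#'   linkages 3 -> 2 ("first") and 2 -> 1 ("second"). After canonicalization
#'   of a branched trisaccharide, residue 2 is the first-branch donor and
#'   residue 3 the middle (bracketed) donor, both linked to residue 1.
#' @examples
#' s <- oligo_structure(
#'   residues = list(residue("Glc", "alpha"), residue("Glc", "beta")),
#'   linkages = list(list(donor = 2, acceptor = 1, position = 4))
#' )
#' format_structure(s)
#' @export
oligo_structure <- function(residues, linkages) {
  n <- length(residues)
  if (!n %in% c(2L, 3L)) {
    abort("an oligo_structure has 2 or 3 residues", class = "glyco_domain_error")
  }
  if (!all(vapply(residues, inherits, logical(1), "glyco_residue"))) {
    abort("residues must be glyco_residue objects", class = "glyco_domain_error")
  }
  if (length(linkages) != n - 1L) {
    abort(sprintf("%d residues require %d linkage(s)", n, n - 1L),
          class = "glyco_domain_error")
  }
  linkages <- lapply(linkages, function(l) {
    l$donor <- as.integer(l$donor); l$acceptor <- as.integer(l$acceptor)
    l$position <- as.integer(l$position)
    if (l$donor == l$acceptor) abort("a residue cannot glycosylate itself",
                                     class = "glyco_domain_error")
    if (!l$position %in% linkage_positions) {
      abort(sprintf("linkage position %d not in {2,3,4,6}", l$position),
            class = "glyco_domain_error")
    }
    l$anomer <- residues[[l$donor]]$anomer
    l
  })

  if (n == 2L) {
    lk <- linkages[[1]]
    if (!(lk$donor == 2L && lk$acceptor == 1L)) {
      abort("disaccharide linkage must run 2 -> 1 (donor -> reducing end)",
            class = "glyco_domain_error")
    }
    chain <- "not_applicable"
  } else {
    acceptors <- vapply(linkages, `[[`, integer(1), "acceptor")
    donors <- vapply(linkages, `[[`, integer(1), "donor")
    if (all(acceptors == 1L)) {
      chain <- "branched"
      if (!setequal(donors, c(2L, 3L))) {
        abort("branched trisaccharide needs donors 2 and 3 on the reducing end",
              class = "glyco_domain_error")
      }
      pos <- vapply(linkages, `[[`, integer(1), "position")
      if (pos[1] == pos[2]) {
        abort("branched linkages must attach at distinct positions",
              class = "glyco_domain_error")
      }
      # canonical branch order: ascending linkage position; donor of the
      # lower-position (first) branch becomes residue 2
      ord <- order(pos)
      linkages <- linkages[ord]
      if (linkages[[1]]$donor != 2L) {
        residues <- residues[c(1L, 3L, 2L)]
        linkages <- lapply(linkages, function(l) {
          l$donor <- c(1L, 3L, 2L)[l$donor]; l
        })
      }
    } else {
      # linear: first (3) -> middle (2) -> reducing (1)
      key <- paste(sort(paste(donors, acceptors, sep = ">")), collapse = ",")
      if (key != "2>1,3>2") {
        abort("linear trisaccharide linkages must run 3 -> 2 and 2 -> 1",
              class = "glyco_domain_error")
      }
      chain <- "linear"
      linkages <- linkages[order(-donors)]  # first linkage (3->2) first
    }
  }

  # substituted acceptor positions must be free
  for (l in linkages) {
    acc <- residues[[l$acceptor]]
    taken <- c(acc$o_methyl, if (acc$n_acetylated) 2L)
    if (l$position %in% taken) {
      abort(sprintf("acceptor position %d is already substituted", l$position),
            class = "glyco_domain_error")
    }
  }
  for (i in seq_len(n)[-1]) {
    if (1L %in% residues[[i]]$o_methyl) {
      abort("anomeric O-methylation is only allowed on the reducing end",
            class = "glyco_domain_error")
    }
  }
  # two linkages on the same acceptor at the same position already excluded;
  # linear middle residue: acceptor position must not collide with its own NAc
  structure(
    list(residues = residues, linkages = linkages, chain = chain,
         reducing_anomer = residues[[1]]$anomer),
    class = "oligo_structure"
  )
}

#' @export
print.oligo_structure <- function(x, ...) {
  cat("<oligo_structure> ", format_structure(x), "\n", sep = "")
  invisible(x)
}

format_residue <- function(r, reducing = FALSE) {
  ring_ome <- setdiff(r$o_methyl, 1L)
  tok <- paste0(substr(r$anomer, 1, 1), "-", monomer_dl(r$monomer), "-",
                r$monomer, "p",
                if (r$n_acetylated) "NAc" else "",
                if (length(ring_ome)) paste0(ring_ome, "Me", collapse = "") else "")
  if (reducing && 1L %in% r$o_methyl) tok <- paste0(tok, "-OMe")
  tok
}

#' Render a structure in the package's linear notation
#'
#' The notation writes residues non-reducing-end first, e.g.
#' `"b-D-Glcp-(1->4)-a-D-Glcp"`; a branched trisaccharide brackets its
#' second (higher linkage position) branch:
#' `"a-D-Glcp-(1->2)-[a-D-Glcp-(1->6)]-a-D-Glcp"`. Substituents append to the
#' residue token (`NAc`, `3Me`, ...); an O-methylated reducing anomeric
#' position is written as a trailing `-OMe`. `parse_structure()` inverts this
#' exactly on canonical strings.
#'
#' @param s An [oligo_structure()].
#' @return A single string.
#' @export
format_structure <- function(s) {
  red <- format_residue(s$residues[[1]], reducing = TRUE)
  link_txt <- function(l) sprintf("-(1->%d)-", l$position)
  if (s$chain == "not_applicable") {
    paste0(format_residue(s$residues[[2]]), link_txt(s$linkages[[1]]), red)
  } else if (s$chain == "linear") {
    paste0(format_residue(s$residues[[3]]), link_txt(s$linkages[[1]]),
           format_residue(s$residues[[2]]), link_txt(s$linkages[[2]]), red)
  } else {
    paste0(format_residue(s$residues[[2]]),
           sprintf("-(1->%d)-", s$linkages[[1]]$position),
           "[", format_residue(s$residues[[3]]),
           sprintf("-(1->%d)", s$linkages[[2]]$position), "]-", red)
  }
}

parse_residue_token <- function(tok, reducing = FALSE, context = tok) {
  full <- tok
  ome1 <- FALSE
  if (grepl("-OMe$", tok)) {
    if (!reducing) abort(paste0("anomeric -OMe only allowed on the reducing end: '",
                                full, "'"), class = "glyco_domain_error")
    ome1 <- TRUE
    tok <- sub("-OMe$", "", tok)
  }
  m <- regmatches(tok, regexec(
    "^([ab])-([DL])-(Glc|Gal|Man|Rha|Fuc)p(NAc)?((?:[2346]Me)*)$", tok))[[1]]
  if (length(m) == 0) {
    abort(paste0("cannot parse residue token '", full, "' in '", context, "'"),
          class = "glyco_parse_error")
  }
  mono <- m[4]
  if (m[3] != monomer_dl(mono)) {
    abort(paste0(mono, " must be ", monomer_dl(mono), "-configured ('", full, "')"),
          class = "glyco_domain_error")
  }
  ome <- as.integer(substring(strsplit(m[6], "Me")[[1]], 1, 1))
  ome <- ome[!is.na(ome)]
  residue(mono, if (m[2] == "a") "alpha" else "beta",
          n_acetylated = m[5] == "NAc",
          o_methyl = c(if (ome1) 1L, ome))
}

#' Parse the linear structure notation
#'
#' Inverse of [format_structure()]. Accepts two or three residue tokens joined
#' by `-(1->n)-` linkage segments, with at most one bracketed branch
#' (`A-(1->x)-[B-(1->y)]-C`, both donors on the reducing end C).
#'
#' @param text A structure string, e.g. `"a-L-Fucp-(1->2)-b-D-Galp-(1->3)-b-D-GlcpNAc"`.
#' @return An [oligo_structure()].
#' @examples
#' parse_structure("b-D-Glcp-(1->4)-a-D-Glcp")
#' @export
parse_structure <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  n_link <- lengths(regmatches(text, gregexpr("\\(1->", text)))
  if (n_link > 2) {
    abort(paste0("more than three residues in '", text, "'"),
          class = "glyco_domain_error")
  }
  if (n_link < 1) {
    abort(paste0("no glycosidic linkage found in '", text, "'"),
          class = "glyco_parse_error")
  }
  pos_ok <- function(p) {
    p <- suppressWarnings(as.integer(p))
    if (is.na(p) || !p %in% linkage_positions) {
      abort(paste0("linkage position '", p, "' not in {2,3,4,6} in '", text, "'"),
            class = "glyco_domain_error")
    }
    p
  }
  if (grepl("[", text, fixed = TRUE)) {
    m <- regmatches(text, regexec(
      "^(.+?)-\\(1->([0-9])\\)-\\[(.+?)-\\(1->([0-9])\\)\\]-(.+)$", text))[[1]]
    if (length(m) == 0) {
      abort(paste0("malformed branched notation near '[' in '", text, "'"),
            class = "glyco_parse_error")
    }
    red <- parse_residue_token(m[6], reducing = TRUE, context = text)
    rf <- parse_residue_token(m[2], context = text)
    rs <- parse_residue_token(m[4], context = text)
    return(oligo_structure(
      residues = list(red, rf, rs),
      linkages = list(list(donor = 2, acceptor = 1, position = pos_ok(m[3])),
                      list(donor = 3, acceptor = 1, position = pos_ok(m[5])))
    ))
  }
  if (n_link == 2) {
    m <- regmatches(text, regexec(
      "^(.+?)-\\(1->([0-9])\\)-(.+?)-\\(1->([0-9])\\)-(.+)$", text))[[1]]
    if (length(m) == 0) {
      abort(paste0("malformed trisaccharide notation: '", text, "'"),
            class = "glyco_parse_error")
    }
    red <- parse_residue_token(m[6], reducing = TRUE, context = text)
    mid <- parse_residue_token(m[4], context = text)
    first <- parse_residue_token(m[2], context = text)
    return(oligo_structure(
      residues = list(red, mid, first),
      linkages = list(list(donor = 3, acceptor = 2, position = pos_ok(m[3])),
                      list(donor = 2, acceptor = 1, position = pos_ok(m[5])))
    ))
  }
  m <- regmatches(text, regexec("^(.+?)-\\(1->([0-9])\\)-(.+)$", text))[[1]]
  if (length(m) == 0) {
    abort(paste0("malformed disaccharide notation: '", text, "'"),
          class = "glyco_parse_error")
  }
  red <- parse_residue_token(m[4], reducing = TRUE, context = text)
  donor <- parse_residue_token(m[2], context = text)
  oligo_structure(
    residues = list(red, donor),
    linkages = list(list(donor = 2, acceptor = 1, position = pos_ok(m[3])))
  )
}

#' Derive the nine task labels from a structure
#'
#' Labels follow the single-letter class codes of [glyco_tasks()]. For a
#' disaccharide the four tasks that require three residues (`ano_s`, `f_link`,
#' `m_residue`, `chain_type`) take the class X, its single glycosidic linkage
#' reports as the second linkage (`s_link`, the linkage adjacent to the
#' reducing end) with its anomer under `ano_f`, and the non-reducing residue
#' reports as `f_residue`. For a branched trisaccharide the canonical
#' lower-position branch supplies `f_link`/`ano_f`/`f_residue` and the
#' bracketed branch `s_link`/`ano_s`/`m_residue`.
#'
#' @param s An [oligo_structure()].
#' @return A one-row tibble with the nine label columns of [task_names()].
#' @examples
#' labels_from_structure(parse_structure("b-D-Glcp-(1->4)-a-D-Glcp"))
#' @export
labels_from_structure <- function(s) {
  stopifnot(inherits(s, "oligo_structure"))
  red <- s$residues[[1]]
  if (s$chain == "not_applicable") {
    lk <- s$linkages[[1]]
    tibble(
      ano_f = anomer_class(lk$anomer), ano_s = "X",
      ano_r = anomer_class(s$reducing_anomer),
      f_link = "X", s_link = linkage_class(lk$position),
      red_end = monomer_class(red$monomer), m_residue = "X",
      f_residue = monomer_class(s$residues[[2]]$monomer), chain_type = "X"
    )
  } else {
    l1 <- s$linkages[[1]]; l2 <- s$linkages[[2]]
    first_res <- if (s$chain == "linear") s$residues[[3]] else s$residues[[2]]
    mid_res <- if (s$chain == "linear") s$residues[[2]] else s$residues[[3]]
    tibble(
      ano_f = anomer_class(l1$anomer), ano_s = anomer_class(l2$anomer),
      ano_r = anomer_class(s$reducing_anomer),
      f_link = linkage_class(l1$position), s_link = linkage_class(l2$position),
      red_end = monomer_class(red$monomer),
      m_residue = monomer_class(mid_res$monomer),
      f_residue = monomer_class(first_res$monomer),
      chain_type = if (s$chain == "linear") "A" else "B"
    )
  }
}

n_carbons <- function(s) {
  sum(vapply(s$residues, function(r) {
    6L + 2L * r$n_acetylated + length(r$o_methyl)
  }, integer(1)))
}
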