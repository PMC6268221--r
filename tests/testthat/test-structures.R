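test_that("structure notation parses to the documented topology", {
  di <- parse_structure("b-D-Glcp-(1->4)-a-D-Glcp")
  expect_s3_class(di, "oligo_structure")
  expect_equal(di$chain, "not_applicable")
  expect_equal(length(di$residues), 2L)
  expect_equal(di$linkages[[1]]$position, 4L)
  expect_equal(di$linkages[[1]]$anomer, "beta")
  expect_equal(di$reducing_anomer, "alpha")

  lin <- parse_structure("a-L-Fucp-(1->2)-b-D-Galp-(1->3)-b-D-GlcpNAc")
  expect_equal(lin$chain, "linear")
  expect_equal(lin$residues[[3]]$monomer, "Fuc")   # first
  expect_equal(lin$residues[[2]]$monomer, "Gal")   # middle
  expect_equal(lin$residues[[1]]$monomer, "Glc")   # reducing
  expect_true(lin$residues[[1]]$n_acetylated)

  br <- parse_structure("a-D-Glcp-(1->2)-[a-D-Glcp-(1->6)]-a-D-Glcp")
  expect_equal(br$chain, "branched")
  expect_true(all(vapply(br$linkages, `[[`, integer(1), "acceptor") == 1L))
})

test_that("parse/format round-trips on canonical strings", {
  strings <- c(
    "b-D-Glcp-(1->4)-a-D-Glcp",
    "a-L-Fucp-(1->2)-b-D-Galp-(1->3)-b-D-GlcpNAc",
    "a-D-Glcp-(1->2)-[a-D-Glcp-(1->6)]-a-D-Glcp",
    "a-L-Rhap3Me-(1->3)-b-D-Manp-(1->6)-a-D-Galp-OMe",
    "b-D-GalpNAc-(1->2)-[b-L-Fucp-(1->4)]-b-D-Manp"
  )
  for (s in strings) {
    expect_identical(format_structure(parse_structure(s)), s)
  }
})

test_that("non-canonical branch order is canonicalized by ascending position", {
  # bracketed branch written with the lower position: parser reorders so the
  # first branch is the lower-position one
  s <- parse_structure("a-D-Manp-(1->6)-[b-D-Galp-(1->2)]-a-D-Glcp")
  expect_equal(s$linkages[[1]]$position, 2L)
  expect_equal(s$residues[[2]]$monomer, "Gal")
  expect_identical(format_structure(s),
                   "b-D-Galp-(1->2)-[a-D-Manp-(1->6)]-a-D-Glcp")
})

test_that("malformed or out-of-domain notation fails loudly", {
  expect_error(parse_structure("b-D-Glcp-(1->5)-a-D-Glcp"), class = "glyco_domain_error")
  expect_error(parse_structure("b-D-Xylp-(1->4)-a-D-Glcp"), class = "glyco_parse_error")
  expect_error(parse_structure("b-L-Glcp-(1->4)-a-D-Glcp"), class = "glyco_domain_error")
  expect_error(parse_structure("not a structure"), class = "glyco_parse_error")
  expect_error(
    parse_structure("a-D-Glcp-(1->2)-a-D-Glcp-(1->3)-a-D-Glcp-(1->4)-a-D-Glcp"),
    class = "glyco_domain_error"
  )
  # anomeric O-methyl only on the reducing end
  expect_error(parse_structure("b-D-Glcp-OMe-(1->4)-a-D-Glcp"),
               class = "glyco_domain_error")
})

test_that("residue invariants are enforced", {
  expect_error(residue("Rha", "alpha", n_acetylated = TRUE),
               class = "glyco_domain_error")
  expect_error(residue("Glc", "alpha", n_acetylated = TRUE, o_methyl = 2),
               class = "glyco_domain_error")
  expect_error(residue("Glc", "alpha", o_methyl = 5), class = "glyco_domain_error")
  # substituted acceptor position is blocked
  expect_error(
    oligo_structure(
      residues = list(residue("Glc", "alpha", o_methyl = 4), residue("Gal", "beta")),
      linkages = list(list(donor = 2, acceptor = 1, position = 4))
    ),
    class = "glyco_domain_error"
  )
})

test_that("label derivation matches the disaccharide merging scheme", {
  labs <- labels_from_structure(parse_structure("b-D-Glcp-(1->4)-a-D-Glcp"))
  expect_equal(as.list(labs), list(
    ano_f = "B", ano_s = "X", ano_r = "A", f_link = "X", s_link = "C",
    red_end = "A", m_residue = "X", f_residue = "A", chain_type = "X"
  ))

  labs2 <- labels_from_structure(
    parse_structure("a-L-Fucp-(1->2)-b-D-Galp-(1->3)-b-D-Glcp"))
  expect_equal(as.list(labs2), list(
    ano_f = "A", ano_s = "B", ano_r = "B", f_link = "A", s_link = "B",
    red_end = "A", m_residue = "B", f_residue = "E", chain_type = "A"
  ))

  labs3 <- labels_from_structure(
    parse_structure("a-D-Glcp-(1->2)-[a-D-Glcp-(1->6)]-a-D-Glcp"))
  expect_equal(labs3$chain_type, "B")
  expect_equal(labs3$f_link, "A")  # lower-position branch is the first linkage
  expect_equal(labs3$s_link, "D")
})

test_that("labelling is total, deterministic, and X-patterns match chain length", {
  recs <- small_records(20, 20)
  for (i in seq_len(nrow(recs))) {
    s <- parse_structure(recs$structure[i])
    l1 <- labels_from_structure(s)
    l2 <- labels_from_structure(s)
    expect_identical(l1, l2)
    x_fields <- names(l1)[unlist(l1) == "X"]
    if (length(s$residues) == 2) {
      expect_setequal(x_fields, c("ano_s", "f_link", "m_residue", "chain_type"))
    } else {
      expect_length(x_fields, 0)
    }
  }
})
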