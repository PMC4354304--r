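test_that("a minimal externally-written SBML file reads correctly", {
  sbml <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="mini" fbc:strict="false">
    <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>
    <listOfSpecies>
      <species id="M_A_c" compartment="c" hasOnlySubstanceUnits="false"
               boundaryCondition="false" constant="false"/>
      <species id="M_B_c" compartment="c" hasOnlySubstanceUnits="false"
               boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="R_v1" reversible="false" fast="false">
        <listOfReactants>
          <speciesReference species="M_A_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_B_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
    </listOfReactions>
  </model>
</sbml>'
  tf <- tempfile(fileext = ".xml")
  writeLines(sbml, tf)
  m <- read_model(tf)
  expect_equal(nrow(m$metabolites), 2)
  expect_equal(nrow(m$reactions), 1)
  expect_false(m$reactions$reversible[1])
  expect_equal(sort(names(m$reactions$stoich[[1]])), c("M_A_c", "M_B_c"))
})

test_that("TSV round-trip preserves a one-reaction model exactly", {
  m <- hand_model(list(
    v1 = list(stoich = c("A[c]" = -1, "B[c]" = 2), gpr = "g1 or g2")))
  tf <- tempfile(fileext = ".tsv")
  write_model(m, tf)
  m2 <- read_model(tf)
  expect_identical(m2$reactions$id, "v1")
  s <- m2$reactions$stoich[[1]]
  expect_equal(s[["A[c]"]], -1)
  expect_equal(s[["B[c]"]], 2)
  expect_identical(sort(m2$genes), c("g1", "g2"))
})

test_that("both formats round-trip random 50-reaction models field by field", {
  spec <- fixture_spec(seed = 21, n_reactions = 50, n_pathways = 6,
                       n_core = 3)
  m <- make_model(spec)
  for (fmt in c("tsv", "sbml")) {
    tf <- tempfile(fileext = if (fmt == "sbml") ".xml" else ".tsv")
    write_model(m, tf, fmt)
    m2 <- read_model(tf, fmt)
    expect_identical(sort(m2$reactions$id), sort(m$reactions$id))
    expect_identical(sort(m2$metabolites$id), sort(m$metabolites$id))
    expect_identical(m2$biomass_id, m$biomass_id)
    expect_identical(sort(m2$genes), sort(m$genes))
    for (id in m$reactions$id) {
      k1 <- match(id, m$reactions$id); k2 <- match(id, m2$reactions$id)
      s1 <- m$reactions$stoich[[k1]]; s2 <- m2$reactions$stoich[[k2]]
      expect_identical(sort(names(s1)), sort(names(s2)))
      expect_equal(unname(s2[names(s1)]), unname(s1), tolerance = 1e-11)
      expect_identical(m2$reactions$reversible[k2],
                       m$reactions$reversible[k1])
      expect_identical(m2$reactions$role[k2], m$reactions$role[k1])
    }
  }
})

test_that("multiple seeds round-trip both formats (structure identity)", {
  for (seed in 1:8) {
    m <- make_model(fixture_spec(seed = seed, n_reactions = 12,
                                 n_pathways = 3, n_core = 1,
                                 reversible_fraction = 0.3))
    for (fmt in c("tsv", "sbml")) {
      tf <- tempfile(fileext = if (fmt == "sbml") ".xml" else ".tsv")
      write_model(m, tf, fmt)
      m2 <- read_model(tf, fmt)
      expect_identical(sort(m2$reactions$id), sort(m$reactions$id))
      expect_identical(m2$biomass_id, m$biomass_id)
      expect_identical(sort(m2$genes), sort(m$genes))
    }
  }
})

test_that("GPR strings survive the SBML gene-association encoding", {
  m <- hand_model(list(
    r1 = list(stoich = c("A[c]" = -1, "B[c]" = 1),
              gpr = "gx1 and (gx2 or gx3)"),
    r2 = list(stoich = c("B[c]" = -1, "C[c]" = 1),
              gpr = "(gy1 and gy2) or gy3")))
  tf <- tempfile(fileext = ".xml")
  write_model(m, tf)
  m2 <- read_model(tf)
  for (id in c("r1", "r2")) {
    g1 <- m$reactions$gpr_dnf[[match(id, m$reactions$id)]]
    g2 <- m2$reactions$gpr_dnf[[match(id, m2$reactions$id)]]
    genes <- sort(gpr_genes(g1))
    expect_identical(sort(gpr_genes(g2)), genes)
    for (mask in 0:(2^length(genes) - 1)) {
      present <- genes[bitwAnd(mask, 2^(seq_along(genes) - 1)) > 0]
      expect_identical(eval_gpr(g1, present), eval_gpr(g2, present))
    }
  }
})

test_that("written SBML is readable by an independent parser (cobrapy)", {
  m <- make_model(fixture_spec(seed = 5, n_reactions = 12, n_pathways = 3,
                               n_core = 2))
  tf <- tempfile(fileext = ".xml")
  write_model(m, tf)
  py <- Sys.which(c("python3", "python"))
  py <- py[nzchar(py)][1]
  script <- sprintf(
    "import cobra, warnings, sys\nwarnings.filterwarnings('ignore')\nm = cobra.io.read_sbml_model('%s')\nprint(len(m.reactions), len(m.metabolites), len(m.genes))",
    tf)
  out <- suppressWarnings(system2(py, c("-c", shQuote(script)),
                                  stdout = TRUE, stderr = FALSE))
  nums <- as.integer(strsplit(tail(out, 1), " ")[[1]])
  expect_equal(nums[1], nrow(m$reactions))
  expect_equal(nums[2], nrow(m$metabolites))
  expect_equal(nums[3], length(m$genes))
})

test_that("malformed inputs give informative errors", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("id\tequation", "r1\tfoo bar"), tf)
  expect_error(read_model(tf), "no arrow")
  writeLines(c("id\tequation", "r1\t(x) A[c] => B[c]"), tf)
  expect_error(read_model(tf), "malformed stoichiometry|r1")
  expect_error(read_model(tempfile()), "not found")
  # duplicate reaction ids
  m <- hand_model(list(v1 = list(stoich = c("A[c]" = -1, "B[c]" = 1))))
  m$reactions <- rbind(m$reactions, m$reactions)
  expect_error(validate_model(m), "duplicate reaction ids")
})

test_that("media files validate and round-trip", {
  tf <- tempfile(fileext = ".tsv")
  write_media(media_of(c("A[e]", "B[e]"), c(10, 20)), tf)
  med <- read_media(tf)
  expect_equal(med$max_uptake, c(10, 20))
  writeLines(c("metabolite_id\tmax_uptake", "A[e]\t-5"), tf)
  expect_error(read_media(tf), "non-negative")
})

test_that("flux tables read with and without id mapping", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tflux", "assay1\t2.5", "assay2\t-1"), tf)
  v <- read_fluxes(tf)
  expect_equal(unname(v), c(2.5, -1))
  mp <- tempfile(fileext = ".tsv")
  writeLines(c("from\tto", "assay1\tR1"), mp)
  v2 <- read_fluxes(tf, map = mp)
  expect_identical(names(v2), c("R1", "assay2"))
})
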