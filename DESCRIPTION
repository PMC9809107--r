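Package: pgtsr
Title: Breakpoint Mapping and Carrier Phasing for Reciprocal Translocations in PGT-SR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for preimplantation genetic testing of balanced reciprocal
    translocation carriers (PGT-SR). Identifies reference embryos from
    unbalanced copy-number profiles, localizes translocation breakpoints both
    from CNV segment boundaries (kilobase windows) and from split long-read
    junctions (single-base resolution), phases the carrier parent's
    derivative-chromosome haplotypes from reference embryos or directly from
    junction-spanning long reads, and calls each euploid embryo carrier or
    non-carrier. Includes a synthetic pedigree simulator with meiotic
    segregation of the translocation quadrivalent, overdispersed bin counts,
    allele dropout at SNPs, and junction-spanning long reads with full ground
    truth, plus a parser/serializer for clinical-style karyotype segment
    strings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
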