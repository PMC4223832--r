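#' Published self-targeting spacer worked examples
#'
#' Curated spacer / chromosomal-region sequence pairs for three
#' self-targeting spacers reported in Salinispora arenicola: an
#' adenylosuccinate lyase and a 23S rRNA methyltransferase match in strains
#' CNH-964 and CNP-105, and a cytochrome P450 match in strain CNX-481. The
#' chromosomal regions include a few adjacent nucleotides on either side of
#' the matched span. The first two spacers occur as exact full-length
#' substrings of their regions (perfect hits); the cytochrome P450 pair
#' shares only a 32-nt exact span (a partial hit under the 18-nt rule),
#' which is the behaviour this package treats as authoritative for that
#' pair.
#'
#' @return data.frame with columns `strain`, `gene`, `spacer`, `region`.
#' @export
self_targeting_examples <- function() {
  data.frame(
    strain = c("S. arenicola CNH-964/CNP-105",
               "S. arenicola CNH-964/CNP-105",
               "S. arenicola CNX-481"),
    gene = c("adenylosuccinate lyase",
             "23S rRNA methyltransferase",
             "cytochrome P450"),
    spacer = c(
      "GCCCACCTTGCCGTGCCACCACGCCTCCCGCACCTCGTTG",
      "CCGAGCGGGTCGAGCTGACCGTCGGGGCGGTGGCCCCGGG",
      "TACCGACGCAGCCATAACTCGTGCTAGGACGGCTGATGGC"
    ),
    region = c(
      "TGCTGCTGCCCACCTTGCCGTGCCACCACGCCTCCCGCACCTCGTTGAACTCCG",
      "GCGGAGGCCGAGCGGGTCGAGCTGACCGTCGGGGCGGTGGCCCCGGGCGGGCAC",
      "TACCGACGCAGCCATAACTCGTGCTAGGACGGTGCCCGCG"
    ),
    stringsAsFactors = FALSE
  )
}
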