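#' Telomeric extension coordinates of the O. tipulae CEW1 assembly
#'
#' Published per-arm telomere repeat addition-site coordinates for the six
#' chromosomes of the telomere-to-telomere *Oscheius tipulae* CEW1
#' assembly: for each chromosome arm, the subtelomeric extension start site
#' (the internal site, where telomeric hexamer repeat is added in
#' short-form chromosomes), the external TTAGGC repeat addition site, the
#' extension span and the external repeat span. Coordinates refer to the
#' full chromosome sequence including terminal repeat. The Otip_IV L
#' extension start site is stored as 39,782, the value implied by its span
#' and external site.
#'
#' @return data.frame with columns `chromosome`, `arm`, `extension_span`,
#'   `extension_start_site`, `external_addition_site`,
#'   `external_repeat_span` (12 rows).
#' @seealso [compute_extension_spans()], which reproduces the
#'   `extension_span` column from the two site columns.
#' @examples
#' tel <- otipulae_telomere_extensions()
#' sum(tel$extension_span)  # 348636
#' @export
otipulae_telomere_extensions <- function() {
  read.delim(system.file("extdata", "otipulae_telomere_extensions.tsv",
                         package = "nigontools"),
             stringsAsFactors = FALSE)
}
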