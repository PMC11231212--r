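#' @importFrom data.table :=
#' @importFrom stats phyper p.adjust
#' @importFrom utils packageVersion
NULL

# data.table non-standard evaluation column names
utils::globalVariables(c("rank", "p_adjusted", "n", "id", "label",
                         "node_type", "p_value", "pathway"))
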