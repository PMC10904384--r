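# Classed error conditions so callers (and tests) can dispatch on failure
# kind rather than on message text.

gsfcError <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "gammaSFC_error")))
}

formatError       <- function(msg) gsfcError(msg, "gsfc_format_error")
validationError   <- function(msg) gsfcError(msg, "gsfc_validation_error")
parameterError    <- function(msg) gsfcError(msg, "gsfc_parameter_error")
densityError      <- function(msg) gsfcError(msg, "gsfc_density_error")
degenerateNodeError  <- function(msg) gsfcError(msg, "gsfc_degenerate_node_error")
degenerateGraphError <- function(msg) gsfcError(msg, "gsfc_degenerate_graph_error")
emptyGraphError   <- function(msg) gsfcError(msg, "gsfc_empty_graph_error")
undefinedDiceError <- function(msg) gsfcError(msg, "gsfc_undefined_dice_error")
geneMatchError    <- function(msg) gsfcError(msg, "gsfc_gene_match_error")
insufficientDataError <- function(msg) gsfcError(msg, "gsfc_insufficient_data_error")
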