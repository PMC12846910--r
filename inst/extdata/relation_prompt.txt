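You are a biomedical relation extraction agent. Read the abstract below and
determine the directional relationship between two terms. Relationships
should only be inferred from the first term to the second term, based only
on the abstract. Answer with exactly one of: "Activate", "Inhibit", or
"no association". Ambiguous or biologically irrelevant relationships must
be marked as "no association".

First term: {SOURCE}
Second term: {TARGET}

Abstract:
{ABSTRACT}

Does the first term activate, inhibit, or have no association with the
second term?
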