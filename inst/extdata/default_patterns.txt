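# Default lexical causal patterns.
# One template per line; {CAUSE} and {EFFECT} mark the slots ({C}/{E} allowed).
# The slot names carry the causal direction, so passive templates orient
# correctly. Replace or extend this file via read_patterns(path).
{CAUSE} causes {EFFECT}
{CAUSE} can cause {EFFECT}
{CAUSE} may cause {EFFECT}
{CAUSE} leads to {EFFECT}
{CAUSE} can lead to {EFFECT}
{CAUSE} results in {EFFECT}
{CAUSE} is a cause of {EFFECT}
{CAUSE}-induced {EFFECT}
{EFFECT} caused by {CAUSE}
{EFFECT} due to {CAUSE}
{EFFECT} secondary to {CAUSE}
{EFFECT} resulting from {CAUSE}
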