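code,redox
NAD,oxidized
NAI,reduced
NAJ,reduced
NAP,oxidized
NDP,reduced
TAP,oxidized
LAC,reduced
PYR,oxidized
FMT,reduced
AKG,oxidized
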