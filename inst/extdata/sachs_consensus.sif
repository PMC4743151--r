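PKC p Raf
PKC p Mek
PKC p JNK
PKC p P38
PKC p PKA
PKA p Raf
PKA p Mek
PKA p ERK
PKA p AKT
PKA p JNK
PKA p P38
Raf p Mek
Mek p ERK
ERK p AKT
PLCg p PIP2
PLCg p PIP3
PIP3 p PIP2
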