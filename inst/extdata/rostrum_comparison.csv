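specimen,measurement,value_mm,flag
MUSM 1609,Length of rostrum (A),798,
MUSM 1609,Width of rostrum base at level antorbital notch (B),214,
MUSM 1609,Width of rostrum at midlength (C),57,
MUSM 1609,Length of symphyseal portion of mandible (D),330,+
MUSM 1037,Length of rostrum (A),844,
MUSM 1037,Width of rostrum base at level antorbital notch (B),217,
MUSM 1037,Width of rostrum at midlength (C),69,
MUSM 1037,Length of symphyseal portion of mandible (D),385,
MUSM 1038,Length of rostrum (A),795,
MUSM 1038,Width of rostrum base at level antorbital notch (B),208,
MUSM 1038,Width of rostrum at midlength (C),64,
MUSM 1038,Length of symphyseal portion of mandible (D),390,
MNHN SAS941,Length of rostrum (A),685,*
MNHN SAS941,Length of symphyseal portion of mandible (D),310,
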