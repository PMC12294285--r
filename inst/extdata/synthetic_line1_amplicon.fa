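>synthetic_LINE1_amplicon_160bp synthetic stand-in; CpG cytosines at 66 (MluCI-reporting) and 81 (TaqI-reporting)
TGGATTGGATTGGATTGGATTGGATTGGATTGGATTGGATTGGATTGGATTGGATTGGATTGAATCGGTGGATTGGATTT
CGATGGATTGGATTGGATTGGATTGGATTGGATTGGATTGGATTGGATTGGATTGGATTGGATTGGATTGGATTGGATTG
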