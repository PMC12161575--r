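>synthetic_site_01 constructed stand-in, not a curated site
TTAGGTTAGGCTAACCTAA
>synthetic_site_02 constructed stand-in, not a curated site
TTAGGTTAGGCTAACCTAA
>synthetic_site_03 constructed stand-in, not a curated site
TAAGGTTAGGCTAACCTAA
>synthetic_site_04 constructed stand-in, not a curated site
TTAGGTTAGGCTAACCTAT
>synthetic_site_05 constructed stand-in, not a curated site
TTAGGTGAGGCTAACCTAA
>synthetic_site_06 constructed stand-in, not a curated site
TTAGGTTAGCCTAACCTAA
>synthetic_site_07 constructed stand-in, not a curated site
CTAGGTTAGGCTAACCTAA
>synthetic_site_08 constructed stand-in, not a curated site
TTAGGTTAGGCTAACCTGA
>synthetic_site_09 constructed stand-in, not a curated site
TTAGGTTAGGTTAACCTAA
>synthetic_site_10 constructed stand-in, not a curated site
TTACGTTAGGCTAACGTAA
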