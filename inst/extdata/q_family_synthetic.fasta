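>Q_synthetic synthetic stand-in; His-tag 1-16, coiled-coil 17-54, register offset 0
MRGSHHHHHHGSGSGSIRELQREMASVQRELERVEEKVKNLSEKINEVKGSIQD
>Q4_synthetic synthetic stand-in; His-tag 1-16, coiled-coil 17-54, register offset 0
MRGSHHHHHHGSGSGSIKKLQEAMKEIQEALKKTQETMKDLNETIKELNKTIED
>Q8_synthetic synthetic stand-in; His-tag 1-16, coiled-coil 17-54, register offset 0
MRGSHHHHHHGSGSGSIKKLQKAMKKIQKALKKIQETMEDLNETIDELNETIED
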