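>synthetic_NTstar_FlSp_like synthetic stand-in sequence (not a natural spidroin NT; designed charge profile: 25 charged residues, net -7)
QAGNSSNSNLFRGIQNTSQKGDANIVAQQNQSAALIDDAIQQVSQSAIVAAQDGQVGEGNVVNMTGAEKYSILTTEASREGKVHAYEQAANIGDSTQSEAAAQTGSKAVDRALFFHFLSNQDDKKVLDNADQSSLLQ
>synthetic_NTstar_MaSp_like synthetic stand-in sequence (not a natural spidroin NT; designed charge profile: 11 charged residues, net -5)
ANSADVAAQNASAGAANEGAQLFNAQQDYEQAPVSQTLIKNFVSVSVFNSNAGNNASFMNYTTKAAAFQAGAADGNAASAYLGDQNGSTLNDYLANNASAATFQLPESGAVFLLLNGNQVTNTSLVAKLS
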