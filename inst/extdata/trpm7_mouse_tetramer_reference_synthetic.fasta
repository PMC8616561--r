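>TRPM7_MOUSE_SYNTHETIC synthetic surrogate subunit, 1863 aa, average mass ~212.4 kDa (not the canonical UniProt sequence)
TARAPGDERWPGLTASLKHEVLLLRTKWDLPLLDPPFLGGDTPIPSKKEDNDGAISCVNV
ENGQQNADVAPSLKEPEISLKSDYILIFPTEDRVMAHVEVVIESLAFPTPPYQQMTGEKI
FPAGAFSDQHKDFMTEHYLFLGTLYSLPVRHFIPSWLLLFRVATFAVSPPLKFNVNEADF
EGVFKIHILEKQKVALDSGTILMKFLVSVCGSSNGDGNPPTWLSNARVPGWPAPQTIHLT
DSRGRLERVPVPHCILTIVKGTTTDTDRSQLSAEQASVRAQGPWSLDSLHLWMSNCVTSI
VHRNCGSVQGPATAWSELAEQKCRLYFKERLDDKVIFLHLIYESVHLSDFRSDMEIFNRL
FQWKECKPLRAQHAMQFGKLQLRLKYDYFQTWFRLVRKTKPVWAFIEERAMGEEQRNCAE
RSPLQEESTVPALPAPYESSGRLMHYAWFGPAASDLCVLANSKSAFQPDPQTQRAQSLQA
WQPSMYGFERKLELNLCDSHLTRWRVVVFPDRPAPHSHVCKLFQPENWGHNDPKKEKRLL
WLSLGLGDAFAKFLKRKELLPYLYKNSIRLAGTQWHQITEGRLNPPTAPNTDFTGYGSEC
IRDIDPSKCKNQRRETKLSDLTWSVDWKDYKVSLYIYPSQEGELDHDCQKTQGRREFVLH
LGNCLKRWPWLAYYISSSRVNEIPDPQHGMSFDLKVRLALCEEGRQSLVRTKDVTTQQYV
RTTIDLARRMTECMAFTPKVHLETSEGVPVVCNTELWVNMAEQIYTRLPREDYLTGEPGV
TAKFYIDCVVHYLKHPFQESTGTWAMSSARAEILPVQCKKDRVMMTEPNAIQLFHFQAAH
QQHVVLFLEDVCEPNMFVDVCQSEKPELQQLAKSDDPVLENPYQSYRRRLNVLIQSTVPA
PVRRSWLKVSLAENPFSVGIHEDWNSAVKFGKMVYDQLNEPLRDKGGMPPPFVDQERGEK
PCMGFVMSRRYFANRQSARVSAQYIGDLDEEYWCVWSTGHRRVPSDMKQTNGNMLSIGAY
GQTGFKAWMSCLRLQATQIEVFPLPLLDENDQEIKKYTTARSKHGPHQLPSAANASAKSY
LVIKTYFDLFIVGVRKETHNLKANRLESEHYAALSRSGLYSHHASLCKDGTDLAARSPSY
STHRFFKARSREGGDSWTCLNYVFGWHARLNAILAVEDKELQFYKELKKYSQANPSRQYW
PSDSLLKRGYRQLIFTMVNDLRHPSRNYNTYYEAQSTGESSWAIVGSLGLFTSRARPEHD
IAWRKEAPEGVDGMRRGRFLAWVTNVNPRRGVLQLREGEFLALELDEELYRYSVHIQDFF
GNCPNAVQSAFPAGHLKTSTIASGVGKSDQNLQYDMVYRLKVHVAYKSEAGPVLLILPHI
AKSGKLTAIEVIISQSLDMVYLLYFPLGQTVQLSIEGGEPLLRHTASAEDTATPTFNHLE
LPKGVRHLPVHPLLAFLPKLSKYHCYSRHLRLFYYAAPLEWLAHKNSDDLGNEPLVKLCG
LGAPNYYFLPQGSSQYRVFFDELPNSDTVSATGQDGPLQFLMIICACFELYVSAIGLESE
LGGYDAPTARRTLHPATQREQVTDWWTPEYSSTRATSMEAEVLTFVGGVSLPGPACLMEE
RPYERLSSEGITKEKSLDAVMYVGIKDEADLFSLLLTRWGNIQLFDEVTMKDESPGFRDK
PGEITVQKSIWHQDTLDPSEYSMYLAFVQWILKFVKEEKLITESKVPIYYSDQRNSKHQF
PCSAIIMSDCVHIWQNVPFKQQFIYDPGGLKNSASFLERQRSDDPRKGPLLKEPDARNCM
YHGHKPVLGECNYVTGISSRQRVTVKPSVLETNTCQAPFHTIKIQKVQLAYGATIVNEPS
ELE
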