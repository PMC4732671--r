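>GusA_syn
MFQWEKVGAKEFIISFCVARTVGLQRGSLWSIQWPRAGVNSDMYLIPKAKTVESGGAAFL
SPGKDFLFSSRNQHEGFTDAPASSSRNEEFVSEIYMVFKSLGLFRLVPVLAGKWEDKIYG
ILRRGGTFKANQVYVASTMEAVWFATGAVIIGVLRSVITHNLLDLSISPDEIEKGSHGAL
KTSHYPLTYKSGPDGVDGFTQYRYRLAPADEVALLERIDLADAVRRDNYSRSKLASEDYY
GDTTMIFTGLEFDLGWEVIGLGIGEYLSASEINIPIVIAFYLNSKVIVMSIDQIKILVEG
FNSHGLDERDMATVGDPIAASSNVEGAHPVEEGAEADQQLSTAESSAAILLIKNKMSKED
WEKRLSVGVEKRFRPTIQRTKGNPETSGELLDIGNGENALLYLLDEIALGLNLHNTTIDE
NIGGLKLSAGRWGSTQGIAD
>GusB_syn
MPKQGSLIRKFVEDSGKQVEVDDRISEADDNFVAKDVLRLDDQDRDVRSPDNDVVAFHYS
VSAKLMKLEAEVDASGVDESNEGISSFISVYADTASLDDALFQEYVGYSQTRVGIKIPPE
LLLDCKNSPLNRETNEVKRICRDVKQSVEDQATFRLKKPATTVVAGMSVALHIGKNRHSQ
LGDPFLDFARKKIINNRAKKQVKETNTADEMPEAGPPSFQPLQLRTQSSVKSVVQGIVVL
SEMADEFAMDSPMNHWSNLRGPFYSVADVKPGGIDLARIVLYAKSGKLLDYLVDEVSITQ
KDLLRWEGIWGVIIKHRVVTAKDLKRPLKDILHGHMSVKFYLQCDQPKTVIHCGSYARAE
ECTLIDGAAAQGFRSSQVPYDEANEKNLELMHVTPKFSDIAEDIDQTQRA
>H11G11_BG_syn
MPFGSQAYLGPEAWPWVEAIWEMYATEKFIKYCAYKVGGEEPSQDSYPHRDVENTPHEHD
KSIVFQFLLWCHLPVQVLFWWYINKLMQHSYSQLVLATIIQWEPCERGMSMTNTAEASLC
GLTQRGAVVLGSFYENNAPQFSAQSNPLHSYFAVGAEYDSIWKLPDQAIANLCPEYHNQD
LPGERNGEERKYCYYECAFAMVKQAEVSIILEKVELPEIFVAPKTIHCIQRNEPDQFDRQ
EGMSRIWARRDMQSSFNLLSSRPVVDDYRKCGSQSAIQPRAVVSIFFSSQHHGHQHRAQN
KMLWIFTQTRNTMTSISPQLCEKVLPGYEYFHLILVLLWLLHTKMWSKCAWTHNMVDMLE
WHNAETCEAPINAFILKQAATRQRKRETGMLLAAVWNWTAEQPQGIDEKVESGSAPVGCP
>H11G11_transporter_syn
MWVGDFWIFFNPVGHDVADHKQRVLGDYITNDPQADWFWCRIQNMAMYGCQNCSSIQKYP
GYYCENWHVNMKTVKTIHETDSFVCVCAPRQNGHRAPYPCVVKHNRWHADNPRNIHCGEQ
TMSEQSTSPEPHFMFTHSALAFDANLYSKLANNRVAKCFSQQTNKHYRSWRFFCTKICSM
WMNNTYLSCNSMPKFTMIGLFKCLFVTKATWFSQMCTIINVKWYDGVESTNKNCVTGPTE
FNQLNPVNCDIKCDSTHMSRGVWHCRETNYFIWVVYLDPYTSIKCMVFIIEYCPAHGVGQ
KHTFRRKKDALTDITWWGFPQFMIIIMRWKIEIINFKNRDTWQLHKLSNNPDNQPWTCEM
SEEEEFYIALEINHIGSPKPRLPCFNSNRSHQDMDVFQHLETLARIRFAQYMSIGLLSSC
GTWLAMLWVY
>C7D2_BG_syn
MPFGVQLYFPPELENRPETLAEMYATVKAIKIAAYKVGVEQPSVDYPIDKYSSSLEVEKA
KSIVSNNKLTCDAADCQYFKYQINFICQHSYSFLVLAHISVKRPCFERMSTTYLAEAYLM
GLMASLQFDLGSRAEFNDPKFSIQSAPLFSRAAIDTPIDSSRVLTFQAIAAQCRYLLEEL
FFLESVQPENLECYVECAFTFVKPSEVRIKEIKKDLYEINAQLPTGHIIVRNEGQQAVRQ
SQMSRWVERRDHASSMELMSKRHYVRFRVKCVILSAIHQVAEVSPDFKSGVEGLVIRAQN
NALTIFAFTGNIMTSINNQGEEKVLQGGLYFHLVGVGLTLLHTQAESANGLTHPPDAILE
KRVSEADFRVDHANIVTLATFHQAFRETLVLLADQNNQTAEDPMKGGLKPASGNAPAGVP
>C7D2_transporter_syn
MEFGDFGNDANRTGLMRAIHRQEVLLDDQDNPEEEMRFWARIGDTKGTGERDCTLGAKPL
GSEGENTTQHMVAVGIVLIEPSRTTVDGPSDHVRSLPQPPIVIHNRVHEGNPRFVLAGEQ
LMTSNNTPTERYKIMVEEAPNVSLILYAKTLIIRYASCKSEETSKKKDMDRLFLLSYDAM
MAVRTRDTFYTAELVTMFLLFLSLDIYKATITSFEVRRAEVQWISIVDATMVNIVTSGAE
PRLGAEVNNDSKAVDTDSSEGQELIRAQPLGTTTKYRFVKSGIKGCCFVIGSTAEKDVIF
GVSSGKMKLGKEEFSMRGVEKAPPIIAARLIETFRFVPVGAGQVHKLIPNLDNQNESIYM
ELNEAFIIVLEHYHITQEYPCKACLHRQLNKLRVVVVYMLLPLATIRFSQHASLGTERWL
VVRLNLPIKG
>GUS_plasmid_syn
MMHVGSVMAFGNIISFMSHRIISNQDYPLAAIQWPFKWFNSGMYLIDPAKTVGSGKPQPR
GPAMIFMWFSGPQHEEFTDVKASSSLQEGFQFRICFGFKSLGDERRMPVLAGQYPEWIYG
LNVNAGGPYHNQVCHHTMDESITNQECNVIEDKKRSVMRHTLWYLGSSPDEWMEGSQKTL
KTSHYPLGVIRCRDGYDYTDQYRSKGAPADEKAVFERIDVADDQMSQNQSRSKLDYNNKF
YDPTRFMPFLYTDSPQRVIGLIIGKQSNYSWHKIPITAAPYHTPKTIMMSIDMTLPLYQG
FNSHGLDPVDMRHDGMGKAFALIWFGVHHSETRWEADQQLASPEQTAEHVLIKNYTSFED
GELFWDVGVEKRFRPTGQRNKTGLMQSGLCLPIGSGETSFLVGWMEIALMKEILDTFIKC
NPIRLSLSARAWSPEQGHAD
>AFTR_syn
MNIKHEFFIAKWVKPMLENCEKGTQAVENRLAGVMLAVIFFKKYTTTPIFYVKFTRQMPM
APVRPACFAIAIFEHDLDKHLAIGKAVAVEEIRKGNELDHGPGYREDDGGNTDPELFVTV
VTLFGGQYTGSSHRSSDDEAEQALEPAGGMIGGPDPICPSLWVETVSLSNSLISWTQFIE
DDQIIWPLDASNQIYDFIIPGSSILLGASRPKGGLVHMCSVDMHVTILGIDWGFLLGTEK
KSSPQAEGVILLRLVQRFAEIVNTVDNPMKEASFLPTGVDREAEVSLPELVHPGSRAGDS
LAEKLFKQTGTNFNLCFADATRGVGECLWDTAAMVKPFRPRNRQMFQLAY
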