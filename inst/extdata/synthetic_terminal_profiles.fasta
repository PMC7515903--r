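>MaSp_NTD NTD
MRFLLALVALLAPIAEPTKFDVQTFLRHNTPSAFLERSRPQFHQVNFNNLPDHRRPFPPIFQIPRIVGKVRSQQKPDVTA
HITNPPTIGDIEDITTVAHFEPDPTHKEHVEAFNGAADEQANDTAHQQDQPALFNSQNPAKEPRDRADLFQRDQTKIAAI
HIPFNQR
>MaSp_CTD CTD
FRGAIIAQVVRDRTFGGRPSRIEKVVRRNVIIRFITDFSAKATHIALGRTDNNHLHSTDKNRGARAPAEPILQREHVPTI
ESVDKHLSGQQHEDVGLVPD
>MiSp_NTD NTD
MRFLLALVALLAPIAEPTKFDVQTFLRHNTPSAFLERSRPQFHQVNFNNLPDHRRPFPPIFQIPRIVGKVRSQQKPDVTA
HITNPPTIGDIEDITTVAHFEPDPTHKEHVEAFNGAADEQANDTAHQQDQPALFNSQNPAKEPRDRADLFQRDQTKIAAI
HIPFNQR
>MiSp_CTD CTD
RGAIIAQVVRDRTFGGRPSRIEKVVRRNVIIRFITDFSAKATHIALGRTDNNHLHSTDKNRGARAPAEPILQREHVPTIE
SVDKHLSGQQHEDVGLVPDT
>AcSp_NTD NTD
MRFLLALVALLAPIAEPTKFDVQTFLRHNTPSAFLERSRPQFHQVNFNNLPDHRRPFPPIFQIPRIVGKVRSQQKPDVTA
HITNPPTIGDIEDITTVAHFEPDPTHKEHVEAFNGAADEQANDTAHQQDQPALFNSQNPAKEPRDRADLFQRDQTKIAAI
HIPFNQR
>AcSp_CTD CTD
HRGETLSLTVRKGDSPGDPGFVPNPHEAVKTFTTLTQIQVGHGGIFHENTIPLQDSNFSDNHLEKTRIRTLKETPISHKV
NKDNRASKAFKKVVLRQNPA
>CySp_NTD NTD
MRFLLALVALLAPIAEPTKFDVQTFLRHNTPSAFLERSRPQFHQVNFNNLPDHRRPFPPIFQIPRIVGKVRSQQKPDVTA
HITNPPTIGDIEDITTVAHFEPDPTHKEHVEAFNGAADEQANDTAHQQDQPALFNSQNPAKEPRDRADLFQRDQTKIAAI
HIPFNQR
>CySp_CTD CTD
GLRRTIVLPVRHIPESAHENSQITGKSLSGTDRAARVHKVPNNAVSPPADVSKRLENPSQGDNDHPSGLTVTKFQDLKPD
KDQRALSKDHPNDAVFEPQF
>PySp_NTD NTD
MRFLLALVALLAPIAEPTKFDVQTFLRHNTPSAFLERSRPQFHQVNFNNLPDHRRPFPPIFQIPRIVGKVRSQQKPDVTA
HITNPPTIGDIEDITTVAHFEPDPTHKEHVEAFNGAADEQANDTAHQQDQPALFNSQNPAKEPRDRADLFQRDQTKIAAI
HIPFNQR
>PySp_CTD CTD
DRAARVHKVPNNAVSPPADVSKRLENPSQGDNDHPSGLTVTKFQDLKPDKDQRALSKDHPNDAVFEPQFQTFTGESPAEE
KVQLAGENHSGEFLVETQDT
>AgSp_NTD NTD
MRFLLALVALLAPIAEPTKFDVQTFLRHNTPSAFLERSRPQFHQVNFNNLPDHRRPFPPIFQIPRIVGKVRSQQKPDVTA
HITNPPTIGDIEDITTVAHFEPDPTHKEHVEAFNGAADEQANDTAHQQDQPALFNSQNPAKEPRDRADLFQRDQTKIAAI
HIPFNQR
>AgSp_CTD CTD
PADVSKRLENPSQGDNDHPSGLTVTKFQDLKPDKDQRALSKDHPNDAVFEPQFQTFTGESPAEEKVQLAGENHSGEFLVE
TQDTHSRTSEHITHHPHRNHHKSNNVGVKIPDLPKLAGKEREHGSKIVHAQFV
>CrSp_NTD NTD
MRFLLALVALLAPIAEPTKFDVQTFLRHNTPSAFLERSRPQFHQVNFNNLPDHRRPFPPIFQIPRIVGKVRSQQKPDVTA
HITNPPTIGDIEDITTVAHFEPDPTHKEHVEAFNGAADEQANDTAHQQDQPALFNSQNPAKEPRDRADLFQRDQTKIAAI
HIPFNQRFFHINLRARKLPLPKHSSQLENFFVFQRQDTQRHETGHAPFDHDVHNKEVEEEAPVDNPNTQEKNTPLEKGND
RVVRDSNEFPVEAQEDSEPSRRVSSRTIHAKGLPVILGIGPPHFLSTTLHLFHHSVADQLKQAREVENTFQNFRPFLGPS
TAISLDNVGQGSIQERKNHDIPNGSHIRRVFQEENQHFDFLLDVNHFSDLIAGSQQVLVLLETIIEINREFKSTVANQHH
RFLRAKKEEIANGGTSHSKGDVTQLFLIGVKIIPRRHDRTIRHTHAPLVSDGAPALPALFEGSRDLTQILTALPGFLTIG
SATSFRFKRKKPDIRLQNAIKVERLSPDFHVKTHPETLDEKVLHHFTFNDEPENHLRSPGHEHQRIDEIGDAEPTVSQLP
FTGHRRHKTPRGGDPSAGSNEVSPQQHEPDTIILESLNSPFRGAIIAQVVRDRTFGGRPSRIEKVVRRNVIIRFITDFSA
KATHIALGRTDNNHLHSTDKNRGARAPAEPILQREHVPTIESVDKHLSGQQHEDVGLVPD
>CrSp_CTD CTD
KKHDDPVTIDVSIPVHPKVSNFDHQEQFFSHVKNKPTRLVGQGTQPVIQEHSDPQVLTDAKHNSRTSLTEADGSVLDIHI
RHPSGSQHPRQQDILLSRGSVEKFDTQFLFAEVVHPDLVFNQHEISHIESVRVQHQDQHRQLVLFKHDNGEAIPTVQKGN
TKGSPKIGHPEKPIQAFKGIQEHFQGDLHGVGLFANLTDIDEEGGDRDQLNIAHSDLFPHTKDRTNGPFFFSSAIEEGKL
ILNQPGGDDNAEQNKEALLPISIRKALTVPVDANTLQANRHTRTDRIKQADRNRQEHQDNHLEDTANDQNSVDDDEVTFQ
>Pflag_NTD NTD
MRFLLALVALLAPIAEPTKFDVQTFLRHNTPSAFLERSRPQFHQVNFNNLPDHRRPFPPIFQIPRIVGKVRSQQKPDVTA
HITNPPTIGDIEDITTVAHFEPDPTHKEHVEAFNGAADEQANDTAHQQDQPALFNSQNPAKEPRDRADLFQRDQTKIAAI
HIPFNQR
>Pflag_CTD CTD
LSPDFHVKTHPETLDEKVLHHFTFNDEPENHLRSPGHEHQRIDEIGDAEPTVSQLPFTGHRRHKTPRGGDPSAGSNEVSP
QQHEPDTIILESLNSPFRGA
>Flag_NTD NTD
MRFLLALVALLAPIAEPTKFDVQTFLRHNTPSAFLERSRPQFHQVNFNNLPDHRRPFPPIFQIPRIVGKVRSQQKPDVTA
HITNPPTIGDIEDITTVAHFEPDPTHKEHVEAFNGAADEQANDTAHQQDQPALFNSQNPAKEPRDRADLFQRDQTKIAAI
HIPFNQR
>Flag_CTD CTD
DVGLVPDTSDSADDSGKILAVDAQHRLEDTQQEKLPQVDLFAVSGPVTNHSARKFEPKTTSIRQAPRGEVGSVNKDFQLI
EDIDETFPADVVEFQQRRTN
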