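>SINV5_like
HTYQKG-PNCRTY-NTNECPQMKKMDECPQRIRKLCCLESYNCQQSATELNTGCIDKIWECGMNSVRMFH
-RWWTA-NAQTCRLWCCLMSFKPATAAYPVHYTYWYPCMCKRKTDGVYLSGAAATAAANSAGDDQAQEYC
VYQHMAHNAM-VMSIEQI-MGV-GWW-AIQDMG-MYMCEVVLELG-CM-RGHCIAIEWAALAQNSRRGEE
FKVNYSWEDESSICMAKRWT--IMMCNDERM-DA-TSI--YERCGTACVF
>aparavirus_1
HTYQKG-PNCRTF-NTNECPQMKKMDECPQRRRKLCCLESYNCQQSATELNTGCIDKIWECGMNSHRMFH
-RGWTA-NAQQCRLWVCLYSFKPATAAYPVHYTYWYPCMCKRKTDGVYLSGAAATAAANSAGDDQAQEYC
VYQHMAHNLM-VMVIEQI-MGV-GWW-AIQDMG-MYMCEVVLELG-CM-RGHCIAIEFAALAQNSRRGEC
FKVNSSWEDEPDICMAKRWT--IMVCNDERM-DA-TSI--YDRCGCALVF
>aparavirus_2
HTYQKG-PNCRTF-NPNEIRMMKKMDECPQRIRKLCCLESYNCQQSADELNTGCIDKIWECGMNSVRMFH
-RGWCA-NAQTCRLWCCLMSFKPDTAAYPVHYGYWYPCMCKRKRDGVYRSGAAATAAANSAGDDQAQEYC
QYQHLAHNDM-VMSIEQI-MPV-GAW-KIQDMG-MYSCEVALERG-CM-RGHWIAIHWAALAQNSRRGEE
FKVNHSWEDESSICMAKRWT--IMSCNDERM-AL-TSI--CDRCGCAFVF
>cripavirus_1
HAYAKG-WPCFTF-ATSECPEPKVQFKIEQDQIKDPCEESYECQQEQTELKTGCIDKIPELKMNSNKCFH
-RIWCM-WAQHCMLNCFNITTKPATFAYPVLYNIWCAFMCMPDTDHVEASGAAATAAANSAGDDQATEYC
VKQSMNHNAM-VMASEQI-YGN-LAP-DDQDMN-MYMREVVLEYG-QV-MDECCGIEHWALAQTPRLTEE
FKEPYDWEDWSYYCMMKRWA--IMLCNDVGM-FA-FRI--IDRGMIVRVF
>cripavirus_2
HAYAKG-WNCFTF-ATYECPSPKKQFKIEQRQLKDPCEEVYYCQPPQTELYTGCIDKIPELKMNSYKCFH
-RIWCF-WAQHCMLNCFNITTMPATFAYPVLYQFWCYFMCMRDTDYVPASGAAATAAANSAGDDQANEYC
VKQSMIHNHM-VMASEQI-TGN-LAW-DMQDMN-MYMRMVVLEYG-CV-SDDQCGIEHWALAQTPRLTEI
FQEPHDWEDSSVNCMMKDKA--YMLCNDVGM-HF-FRI--IDRGGCWRVF
>cripavirus_3
HAYAKG-WNCFTF-ATSELPSPKKQFKIEQRQIKQPHEESYECQQEQTELWTGCIDEIPELKMNSYKCFH
-RIHCM-WAQHCMLNCFNITTKFATFAYPVLYQHWCPFMCMRGTDRVEASGAAATAAANSAGDDQALEYC
VKQIMDHNAM-FMASEMV-YNN-LAK-DDQDMN-MYMRHQVMEYG-CV-SPECCGIEHWALAQTKRMTEE
FLEPHDFCDWSVICMMKRWA--IMLCNDVGM-HR-FRV--IDRGGCVRVF
>triatovirus_1
HAYAKG-WNCFTF-NTSECPSPKKCFKIEQRQIKNPCEQQYECQQEQCEEKGGCIDKIFELKMNIYKCFH
-RIWCL-WAIHGMLNCFNITTKPATFAYPVLYQIWCPFMCMRDTDQVLPSGAAATAAANSAGDDQANEYG
VEESMIHNHM-VMASEQM-YGK-LAW-DDADDS-MYMREVFWDYG-CV-SDECYGIEHWALAQTPRLTEE
FKEPHYWEDWSVICMMMRWA--LMLCNDVSM-PK-FRI--IDRGGCVVVF
>outgroup_1
WTYWEC-YNWRNF-NINSEPVPKKQFEVPQIYRKDCGHEWCEMDTSETELNWGLINPQPECGMNAVHMFH
-RGHEM-MACINRFYCCNMLDCWKTFYQPVRYQYTYPLQCMDKFHQEYYSGAAATAAANSAGDDQAQETC
PRMNMKGNAS-MASLYQI-GCP-GWW-TIWDMN-PIMCEASVEHG-CN-QYHCGARFKCKLAQGMRYGEE
FVVNYSWADESYICMASRST--FCMVICERM-DW-GSI--IDWCTRACEF
>outgroup_2
YSYQKG-MNCMAF-NLEYCAQSKKQFEFICRQGKDCCHISVEEAQSQYKLNTGCIDKIQECWILSVRTFV
-RCWCY-NAITCGQKRFFCTFNPATFAKTIVKQVWLHCMCQVWTYSVYHSGAAATAAANSAGDDQAQEYP
VYHHQAHYSQ-VMKTKQI-VGN-AWW-DLGDWN-RYVCEWQIEHG-LM-PYHPTAIWWMPLSQTSRRGEE
NKVFCSWEDCSWVSMAKTPF--DMKCLDERM-GV-LIM--SLRCGCACVF
>outgroup_3
YTRCKG-PDCRYF-KDLYCPQMKKQFEDPQRKRINCPHSFYHMVVSQTCANKECDRKYPECGYFSVQMAC
-RCWTA-NAQRCRSKECKMDDKMAVAAKPIHMQYMPICDYMRNTDGVYWSGAAATAAANSAGDDQAQEPC
EYTHLACHLI-RESCLEI-LTN-GKH-TIKDFN-MACCEVVLELY-CM-SGKCIAQEDCALAQYSRGGEY
FSVNYSSIDEHVICAAKAWT--IIMEPDMHA-DA-WSI--SDRCGYHSVC
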