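;; synthetic stand-in RPW8 anchor set (not database sequences)
>Conifer_G1a group=1 synthetic=true
ETTPEYVPTDGNCGAALTGVIHNKLHTQTETDSPVTHAVAGIELKRRFISYYGSGANDAITFSMHYGNDWCATDLGNFHFRWSNYHLHTYVRPPDRCTETDFVWAMNGSYYSEQVEVPCIAKYHCPVN
>Conifer_G1b group=1 synthetic=true
ETTPEYVPTDGNCSAALTGVIHNKLHTQTEIDSPVTHAVAGIELKYRFDSYYWSGAVDKSTFSMHYGNDWCATDLSNFHFYWSNYHLHTYVRPPLRCTETDFVWAMNGSYYSEQVGVPRIAKYHCPVN
>ADR1 group=2 synthetic=true
RKPKDVKFTFMHCWDVDSALMTFYCLTPWDCKFMRFVQQYQEWSKGAGINWIWEPSNVSIICRRNMFWHCNAEVRDPGSAREHKGRIMVHNSMDGNACWTKEANAWAVGSNHVDLSFTKLRDGAQNVI
>Conifer_G2a group=2 synthetic=true
RKPKDVKYTFMHCWDFDSALMTFYCLTPWDCKMMRFVQQYQEWSKWDGINWIWEPSNVSIICRRNMFWHCNAEVRDPGSAREHNGRIMVHNSMDGNACWTKEANAWAVGSNHPDLSFTKLRDGAQNVI
>Conifer_G3a group=3 synthetic=true
GARNFGTKIPKSRLKHECCHIMTDYFPNLTEQDDFCSYHFRQTMQQKSWTMIQRNDRMDKTTVGHDIVEPFKWAIVINCKMMDGSCHELIRERLSLLFQYTEMIDECNKEFLNEWTTDKLVEEPKLAG
>Conifer_G3b group=3 synthetic=true
GARNFGTKIPKSWLKHETCHIMDDYFPNLTEQDDFCSYHFRQTYQQKSWTMIQLNERMDQTTFGHDIVEPFKWAIVINCKMMDGSCHELIRERQGLLFQYYEMIDECNKPFLAEWTLDKLVEEPKLAG
>NRG1 group=4 synthetic=true
WEINTRVAFVCYMPCAVQVWTDHGMKIVGCMQQFVIYDDMEDRMMGICKQRFRSLPHYQRCCQNFQTPVNWTKHHCDDLICESATSICGHSEEHHYAHFYQMNDGATDQARLCQNNWHMCRYMQEFFP
>RPW8.1 group=4 synthetic=true
WEINTRVAFVCYMPCAVQVWTDHNMKIVGCMQQDVIYDDMEDRMMGICKQRFRSLPHYQRCCQNFQDPVNWTKHHCDDLICESATSICGHSEEHHYAAFYQMNDGATDQARLCQNNWHMYRKMQEFFP
>RPW8.2 group=4 synthetic=true
WEINTRVAFVCYMPCAVQVWTDHQMKIVGCMDNFVHYDDMEDRMMHICKQRFRSLNHYQRCCQIFQTPVNWTKHHCRDLICELATSICGHSNENHYAHFYQMQDGATDQARLCQNNWHCCRYMQEFFP
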